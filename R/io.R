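#' Normalize a gene symbol
#'
#' Symbols are compared after uppercasing and trimming surrounding
#' whitespace; no alias mapping is attempted. The operation is idempotent.
#'
#' @param x Character vector of raw symbols.
#' @return Character vector of normalized symbols.
#' @export
#' @examples
#' normalize_symbol(c(" tp53", "Kras "))
normalize_symbol <- function(x) {
  toupper(trimws(as.character(x)))
}

read_tsv_strict <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = NULL,
                    comment.char = "")
}

#' Read a compound table
#'
#' Reads a tab-separated compound table with header columns
#' `compound_id`, `name`, `herbs` (semicolon-separated herb identifiers),
#' `ob` (oral bioavailability, percent), `dl` (drug-likeness in \[0,1\]),
#' `rescued` and `rescue_note`. Empty `ob`/`dl` cells become `NA`
#' (value absent).
#'
#' @param path Path to the TSV file.
#' @return A `compound_table`: data.frame with columns `compound_id`,
#'   `name`, `herbs` (list column of character vectors), `ob`, `dl`
#'   (numeric, `NA` = absent), `rescued` (logical), `rescue_note`.
#' @export
read_compound_table <- function(path) {
  df <- read_tsv_strict(path)
  required <- c("compound_id", "name", "herbs", "ob", "dl",
                "rescued", "rescue_note")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("compound table ", path, ": missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  n <- nrow(df)
  parse_num <- function(cell, col, row) {
    cell <- trimws(cell)
    if (identical(cell, "")) return(NA_real_)
    v <- suppressWarnings(as.numeric(cell))
    if (is.na(v)) {
      stop("compound table row ", row, ": non-numeric ", col,
           " value ", dQuote(cell))
    }
    v
  }
  herbs <- vector("list", n)
  ob <- dl <- numeric(n)
  rescued <- logical(n)
  for (i in seq_len(n)) {
    hs <- trimws(strsplit(df$herbs[i], ";", fixed = TRUE)[[1]])
    hs <- unique(hs[nzchar(hs)])
    if (length(hs) == 0) {
      stop("compound table row ", i, ": empty herbs field")
    }
    herbs[[i]] <- hs
    ob[i] <- parse_num(df$ob[i], "ob", i)
    dl[i] <- parse_num(df$dl[i], "dl", i)
    rescued[i] <- tolower(trimws(df$rescued[i])) %in% c("true", "t", "1", "yes")
  }
  out <- data.frame(compound_id = df$compound_id, name = df$name,
                    stringsAsFactors = FALSE)
  out$herbs <- herbs
  out$ob <- ob
  out$dl <- dl
  out$rescued <- rescued
  out$rescue_note <- df$rescue_note
  validate_compound_table(out)
}

#' Validate a compound table
#'
#' Checks the record invariants: non-empty herb sets, `ob >= 0` and
#' `dl` in \[0,1\] when present, and a non-empty `rescue_note` whenever
#' `rescued` is set.
#'
#' @param df A compound table as returned by [read_compound_table()].
#' @return The validated table, classed `compound_table`.
#' @export
validate_compound_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (anyDuplicated(df$compound_id)) {
    stop("duplicate compound_id: ",
         df$compound_id[duplicated(df$compound_id)][1])
  }
  for (i in seq_len(nrow(df))) {
    if (length(df$herbs[[i]]) == 0) {
      stop("compound ", df$compound_id[i], ": empty herb set")
    }
    if (!is.na(df$ob[i]) && df$ob[i] < 0) {
      stop("compound ", df$compound_id[i], ": negative ob")
    }
    if (!is.na(df$dl[i]) && (df$dl[i] < 0 || df$dl[i] > 1)) {
      stop("compound ", df$compound_id[i], ": dl outside [0,1]")
    }
    if (df$rescued[i] && !nzchar(trimws(df$rescue_note[i]))) {
      stop("compound ", df$compound_id[i], ": rescued without rescue_note")
    }
  }
  class(df) <- c("compound_table", "data.frame")
  df
}

#' Write a compound table
#'
#' Inverse of [read_compound_table()]; herb sets are re-joined with
#' semicolons and absent `ob`/`dl` values become empty cells.
#'
#' @param df A compound table.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_compound_table <- function(df, path) {
  out <- data.frame(
    compound_id = df$compound_id,
    name = df$name,
    herbs = vapply(df$herbs, paste, "", collapse = ";"),
    ob = ifelse(is.na(df$ob), "", format_number(df$ob)),
    dl = ifelse(is.na(df$dl), "", format_number(df$dl)),
    rescued = ifelse(df$rescued, "true", "false"),
    rescue_note = df$rescue_note,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

# fixed-format numbers so that seeded bundles are byte-stable
format_number <- function(x) {
  s <- formatC(x, format = "g", digits = 15)
  trimws(s)
}

#' Read a compound-to-target mapping
#'
#' Two-column TSV with header `compound_id`, `target`; one pair per row.
#' Target symbols are normalized and duplicate pairs collapsed.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `compound_id`, `target`.
#' @export
read_ct_map <- function(path) {
  df <- read_tsv_strict(path)
  missing <- setdiff(c("compound_id", "target"), names(df))
  if (length(missing) > 0) {
    stop("compound-target map ", path, ": missing column(s): ",
         paste(missing, collapse = ", "))
  }
  out <- data.frame(compound_id = trimws(df$compound_id),
                    target = normalize_symbol(df$target),
                    stringsAsFactors = FALSE)
  unique(out)
}

#' Read a protein-protein interaction edge list
#'
#' Accepts either a two-column tab-separated edge list (an optional
#' `source<TAB>target`-style header line is skipped) or SIF lines of the
#' form `A interacts B` (one or more interaction partners per line; a
#' lone node name declares an isolated node). Symbols are normalized on
#' read; self-loops are dropped with a message and duplicate pairs
#' collapsed, yielding a simple undirected graph.
#'
#' @param path Path to the edge file.
#' @return An undirected simple [igraph::graph] whose vertex names are
#'   normalized symbols.
#' @export
read_ppi_edges <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  first <- tolower(trimws(lines[1]))
  if (first %in% c("source\ttarget", "from\tto",
                   "node1\tnode2", "symbol1\tsymbol2")) {
    lines <- lines[-1]
  }
  from <- character(0); to <- character(0)
  isolated <- character(0)
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    tok <- tok[nzchar(tok)]
    if (length(tok) == 1) {
      isolated <- c(isolated, tok)
    } else if (length(tok) == 2) {
      from <- c(from, tok[1]); to <- c(to, tok[2])
    } else if (length(tok) >= 3) {
      # SIF: nodeA relation nodeB [nodeC ...]
      from <- c(from, rep(tok[1], length(tok) - 2))
      to <- c(to, tok[-(1:2)])
    } else {
      stop("malformed interaction line ", i, " in ", path)
    }
  }
  graph_from_symbol_pairs(normalize_symbol(from), normalize_symbol(to),
                          isolated = normalize_symbol(isolated))
}

# Build a simple undirected graph from symbol pairs, dropping self-loops
# (reported via message) and collapsing duplicates.
graph_from_symbol_pairs <- function(from, to, isolated = character(0)) {
  self <- from == to
  if (any(self)) {
    message("dropped ", sum(self), " self-loop(s)")
    from <- from[!self]; to <- to[!self]
  }
  a <- pmin(from, to); b <- pmax(from, to)
  keep <- !duplicated(paste(a, b, sep = "\t"))
  nodes <- sort(unique(c(a, b, isolated)))
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (any(keep)) {
    g <- igraph::add_edges(g, rbind(match(a[keep], nodes),
                                    match(b[keep], nodes)))
  }
  g
}

#' Edge set of a graph as a canonical data.frame
#'
#' @param g An igraph object with vertex names.
#' @return data.frame with columns `from`, `to`, each row sorted so that
#'   `from <= to`, rows in lexicographic order.
#' @export
edge_table <- function(g) {
  if (igraph::ecount(g) == 0) {
    return(data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE))
  }
  el <- igraph::as_edgelist(g)
  df <- data.frame(from = pmin(el[, 1], el[, 2]),
                   to = pmax(el[, 1], el[, 2]), stringsAsFactors = FALSE)
  df <- df[order(df$from, df$to), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a network to disk
#'
#' Supported formats: `"sif"` (lines `A interacts B`, isolated nodes as
#' lone names), `"tsv"` (header `source<TAB>target` plus one edge per
#' row and lone names for isolated nodes), and `"graphml"`. Reading the
#' file back with [read_network()] reconstructs an identical node and
#' edge set; for bipartite networks the `role` vertex attribute
#' (compound/target) survives the GraphML round trip.
#'
#' @param net An igraph object with vertex names.
#' @param path Output path.
#' @param format One of `"sif"`, `"tsv"`, `"graphml"`.
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path, format = c("sif", "tsv", "graphml")) {
  if (!format[1] %in% c("sif", "tsv", "graphml")) {
    stop("unknown network format ", dQuote(format[1]),
         "; supported: sif, tsv, graphml")
  }
  format <- format[1]
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
    return(invisible(path))
  }
  et <- edge_table(net)
  touched <- unique(c(et$from, et$to))
  lone <- setdiff(igraph::V(net)$name, touched)
  lines <- character(0)
  if (format == "sif") {
    if (nrow(et) > 0) lines <- paste(et$from, "interacts", et$to)
  } else {
    lines <- c("source\ttarget",
               if (nrow(et) > 0) paste(et$from, et$to, sep = "\t"))
  }
  writeLines(c(lines, sort(lone)), path)
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path Input path.
#' @param format One of `"sif"`, `"tsv"`, `"graphml"`.
#' @return An igraph object.
#' @export
read_network <- function(path, format = c("sif", "tsv", "graphml")) {
  if (!format[1] %in% c("sif", "tsv", "graphml")) {
    stop("unknown network format ", dQuote(format[1]),
         "; supported: sif, tsv, graphml")
  }
  if (format[1] == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  read_ppi_edges(path)
}

#' Read a gene-set collection in GMT format
#'
#' Standard GMT: `term_id<TAB>description<TAB>gene1<TAB>gene2...`. A
#' category is parsed from a `|`-suffix of the description
#' (`molecular_function_biological_process` or `signaling_pathway`);
#' anything else is classed `other`. Genes are normalized and
#' de-duplicated within each term.
#'
#' @param path Path to the GMT file.
#' @return A `gene_set_collection`: list with elements `ids`,
#'   `description`, `category` (parallel character vectors) and `genes`
#'   (named list of normalized gene vectors).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  ids <- desc <- cat <- character(length(lines))
  genes <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(tok) < 3) {
      stop("GMT line ", i, ": fewer than 3 fields")
    }
    ids[i] <- trimws(tok[1])
    d <- tok[2]
    category <- "other"
    if (grepl("|", d, fixed = TRUE)) {
      parts <- strsplit(d, "|", fixed = TRUE)[[1]]
      suffix <- trimws(parts[length(parts)])
      if (suffix %in% c("molecular_function_biological_process",
                        "signaling_pathway")) {
        category <- suffix
        d <- paste(parts[-length(parts)], collapse = "|")
      }
    }
    desc[i] <- d
    cat[i] <- category
    gs <- unique(normalize_symbol(tok[-(1:2)]))
    gs <- gs[nzchar(gs)]
    if (length(gs) == 0) stop("GMT line ", i, ": term with no genes")
    genes[[i]] <- gs
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("GMT: duplicate term id ", dQuote(dup[1]))
  }
  names(genes) <- ids
  structure(list(ids = ids, description = desc, category = cat,
                 genes = genes),
            class = "gene_set_collection")
}

#' Write a gene-set collection in GMT format
#'
#' @param sets A `gene_set_collection`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  desc <- ifelse(sets$category == "other", sets$description,
                 paste(sets$description, sets$category, sep = "|"))
  lines <- vapply(seq_along(sets$ids), function(i) {
    paste(c(sets$ids[i], desc[i], sets$genes[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$ids), "terms (",
      paste(names(table(x$category)), table(x$category),
            sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' Read a one-symbol-per-line gene list
#'
#' Blank lines and `#` comments are ignored; symbols are normalized and
#' de-duplicated (first occurrence wins).
#'
#' @param path Path to the list file (a single `symbol` header is
#'   skipped when present).
#' @return Character vector of normalized symbols.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0 && tolower(lines[1]) == "symbol") lines <- lines[-1]
  unique(normalize_symbol(lines))
}

#' Read a compound whitelist
#'
#' One compound id per line; `#` comments allowed.
#'
#' @param path Path to the whitelist file.
#' @return Character vector of compound ids.
#' @export
read_whitelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  unique(lines[nzchar(lines)])
}
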