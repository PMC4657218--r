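#' Read a single-locus amino-acid alignment
#'
#' Reads FASTA or relaxed sequential PHYLIP ("ntaxa ncols" header, then
#' one `label sequence` record per taxon, sequence possibly split by
#' whitespace). Taxon order is preserved, residues are uppercased, and
#' `-`, `?`, `X` are treated as non-data states downstream.
#'
#' @param path file path.
#' @param format `"fasta"` or `"phylip-relaxed"`.
#' @param name locus identifier stored on the alignment; defaults to the
#'   file name without extension.
#' @return a [alignment()] object.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip-relaxed"),
                           name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  seqs <- switch(format,
    fasta = parse_fasta(lines, path),
    `phylip-relaxed` = parse_phylip_relaxed(lines, path))
  alignment(seqs, name = name)
}

parse_fasta <- function(lines, path) {
  keep <- !grepl("^\\s*$", lines)
  lines <- lines[keep]
  idx <- which(keep)
  if (length(lines) == 0) stop("no records in ", path)
  hdr <- startsWith(lines, ">")
  if (!hdr[1])
    stop("malformed FASTA in ", path, ": sequence before first header at line ",
         idx[1])
  if (!any(hdr)) stop("no records in ", path)
  labels <- sub("^>\\s*", "", lines[hdr])
  labels <- sub("\\s.*$", "", labels)   # first token is the taxon label
  grp <- cumsum(hdr)
  seqs <- vapply(seq_len(sum(hdr)), function(i) {
    paste(gsub("\\s+", "", lines[!hdr & grp == i]), collapse = "")
  }, character(1))
  empty <- seqs == ""
  if (any(empty))
    stop("malformed FASTA in ", path, ": record(s) without sequence: ",
         paste(labels[empty], collapse = ", "))
  names(seqs) <- labels
  seqs
}

parse_phylip_relaxed <- function(lines, path) {
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0) stop("no records in ", path)
  hd <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hd) != 2 || anyNA(suppressWarnings(as.integer(hd))))
    stop("malformed PHYLIP header in ", path, " at line 1: '", lines[1], "'")
  n <- as.integer(hd[1]); ncols <- as.integer(hd[2])
  body <- lines[-1]
  if (length(body) != n)
    stop("PHYLIP in ", path, ": header declares ", n, " taxa but file has ",
         length(body), " records")
  toks <- strsplit(trimws(body), "\\s+")
  labels <- vapply(toks, `[`, character(1), 1)
  seqs <- vapply(toks, function(tk) paste(tk[-1], collapse = ""), character(1))
  bad <- nchar(seqs) != ncols
  if (any(bad))
    stop("PHYLIP in ", path, ": sequence length differs from header (",
         ncols, ") for taxa: ", paste(labels[bad], collapse = ", "))
  stats::setNames(seqs, labels)
}

#' Write an alignment to FASTA or relaxed PHYLIP
#'
#' Taxon labels containing whitespace are sanitized to underscores; a
#' label collision after sanitization is an error. The PHYLIP header is
#' `"n_taxa n_cols"`.
#'
#' @param aln a [alignment()].
#' @param path output file path.
#' @param format `"fasta"` or `"phylip-relaxed"`.
#' @return invisibly, `path`.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip-relaxed")) {
  format <- match.arg(format)
  labels <- gsub("\\s+", "_", aln_taxa(aln))
  if (anyDuplicated(labels))
    stop("taxon labels collide after whitespace sanitization: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  seqs <- aln_strings(aln)
  out <- switch(format,
    fasta = as.vector(rbind(paste0(">", labels), unname(seqs))),
    `phylip-relaxed` = c(paste(nrow(aln), ncol(aln)),
                         paste(labels, unname(seqs))))
  writeLines(out, path)
  invisible(path)
}

#' Read Newick trees
#'
#' Reads one or more Newick strings. Internal-node labels that parse as
#' numbers are taken as support values; if every numeric support in the
#' file lies in \[0, 1\] the file is assumed to be on the posterior
#' probability scale and supports are rescaled to percent, so bootstrap
#' and posterior-probability inputs are comparable.
#'
#' @param path file with one or more Newick strings.
#' @return a list of `phylo` objects (always a list, even for one tree).
#' @export
read_trees <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!grepl(";", txt)) stop("no Newick trees (no ';') in ", path)
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close)
    stop("unbalanced parentheses in ", path, ": ", n_open, " '(' vs ",
         n_close, "')'")
  trees <- ape::read.tree(text = txt)
  if (is.null(trees)) stop("could not parse Newick in ", path)
  if (inherits(trees, "phylo")) trees <- list(trees) else trees <- unclass(trees)
  # per-file support scale detection: all numeric labels in [0,1] -> x100
  sup <- unlist(lapply(trees, function(tr)
    suppressWarnings(as.numeric(tr$node.label))))
  sup <- sup[is.finite(sup)]
  if (length(sup) > 0 && all(sup >= 0 & sup <= 1)) {
    trees <- lapply(trees, function(tr) {
      v <- suppressWarnings(as.numeric(tr$node.label))
      tr$node.label[is.finite(v)] <- format(v[is.finite(v)] * 100,
                                            trim = TRUE)
      tr
    })
  }
  trees
}

#' Write trees as Newick
#'
#' @param trees a `phylo` or list of `phylo`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_trees <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  class(trees) <- "multiPhylo"
  ape::write.tree(trees, file = path)
  invisible(path)
}

#' Build a partition table for an ordered set of loci
#'
#' Coordinates are 1-based inclusive and tile `1..sum(lengths)` exactly,
#' following the RAxML partition-file convention.
#'
#' @param loci locus names, in concatenation order.
#' @param lengths column counts, same order.
#' @param model model label written in the first field (default
#'   `"AUTO"`).
#' @return a `data.frame` with columns `model`, `locus`, `start`, `end`.
#' @export
partition_table <- function(loci, lengths, model = "AUTO") {
  stopifnot(length(loci) == length(lengths))
  if (anyDuplicated(loci))
    stop("duplicate locus names: ",
         paste(unique(loci[duplicated(loci)]), collapse = ", "))
  if (length(loci) == 0)
    return(data.frame(model = character(0), locus = character(0),
                      start = integer(0), end = integer(0)))
  end <- cumsum(as.integer(lengths))
  start <- c(1L, utils::head(end, -1) + 1L)
  data.frame(model = rep_len(model, length(loci)), locus = loci,
             start = start, end = end, stringsAsFactors = FALSE)
}

validate_partition_table <- function(pt) {
  if (nrow(pt) == 0) return(invisible(pt))
  if (any(pt$end < pt$start)) stop("partition with end < start")
  o <- order(pt$start)
  s <- pt$start[o]; e <- pt$end[o]
  if (s[1] != 1L) stop("partitions do not start at 1")
  if (nrow(pt) > 1 && any(s[-1] != e[-nrow(pt)] + 1L))
    stop("partition ranges overlap or leave gaps")
  invisible(pt)
}

#' Write a RAxML-style partition file
#'
#' One line per locus in the form `MODEL, name = start-end`. Ranges must
#' tile `1..total` contiguously.
#'
#' @param pt a [partition_table()] data frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_partition_table <- function(pt, path) {
  validate_partition_table(pt)
  writeLines(sprintf("%s, %s = %d-%d", pt$model, pt$locus, pt$start, pt$end),
             path)
  invisible(path)
}

#' Read a RAxML-style partition file
#'
#' @param path partition file written by [write_partition_table()].
#' @return a `data.frame` with columns `model`, `locus`, `start`, `end`.
#' @export
read_partition_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0)
    return(partition_table(character(0), integer(0)))
  m <- regmatches(lines,
    regexec("^\\s*([^,]+?)\\s*,\\s*(\\S+)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$",
            lines))
  bad <- vapply(m, length, integer(1)) != 5
  if (any(bad))
    stop("malformed partition line(s): ", paste(lines[bad], collapse = "; "))
  pt <- data.frame(model = vapply(m, `[`, character(1), 2),
                   locus = vapply(m, `[`, character(1), 3),
                   start = as.integer(vapply(m, `[`, character(1), 4)),
                   end = as.integer(vapply(m, `[`, character(1), 5)),
                   stringsAsFactors = FALSE)
  validate_partition_table(pt)
  pt
}
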