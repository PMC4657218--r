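#' Amino-acid alignment container
#'
#' A `locus_alignment` is a character matrix of single residues with one
#' row per taxon (row names are the taxon labels, preserved in input
#' order) and one column per alignment position. Residues are stored
#' uppercase; `-`, `?` and `X` are the missing/non-data states.
#'
#' @param x a named character vector of sequence strings, or a character
#'   matrix of single residues with row names.
#' @param name locus identifier carried in the `"name"` attribute.
#' @return an object of class `locus_alignment`.
#' @examples
#' aln <- alignment(c(t1 = "ACDE", t2 = "ACD-"), name = "loc1")
#' aln_length(aln)
#' aln_taxa(aln)
#' @export
alignment <- function(x, name = "") {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == ""))
      stop("all sequences must be named with taxon labels")
    lens <- nchar(x)
    if (length(unique(lens)) > 1) {
      bad <- names(x)[lens != lens[1]]
      stop("sequences differ in length; offending taxa: ",
           paste(bad, collapse = ", "))
    }
    m <- if (length(x) == 0 || lens[1] == 0)
      matrix(character(0), nrow = length(x), ncol = 0,
             dimnames = list(names(x), NULL))
    else
      matrix(unlist(strsplit(toupper(x), "", fixed = TRUE), use.names = FALSE),
             nrow = length(x), byrow = TRUE, dimnames = list(names(x), NULL))
  } else if (is.matrix(x) && is.character(x)) {
    if (is.null(rownames(x))) stop("matrix must have taxon row names")
    m <- x
    m[] <- toupper(m)
  } else stop("x must be a named character vector or character matrix")
  if (anyDuplicated(rownames(m)))
    stop("duplicate taxon labels: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  structure(m, name = name, class = c("locus_alignment", "matrix", "array"))
}

#' @rdname alignment
#' @param aln a `locus_alignment`.
#' @export
aln_length <- function(aln) ncol(aln)

#' @rdname alignment
#' @export
aln_taxa <- function(aln) rownames(aln)

#' @rdname alignment
#' @export
aln_name <- function(aln) attr(aln, "name")

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("locus alignment '%s': %d taxa x %d columns\n",
              aln_name(x), nrow(x), ncol(x)))
  invisible(x)
}

# the non-data alphabet shared across the package
MISSING_CHARS <- c("-", "?", "X")

#' Logical mask of missing/non-data cells
#'
#' `-`, `?` and `X` (case-insensitive) all count as missing, matching
#' the conventions of trimAl and RAxML input.
#'
#' @param aln a `locus_alignment` (or character matrix of residues).
#' @return logical matrix of the same shape, `TRUE` where the cell is
#'   missing.
#' @export
missing_mask <- function(aln) {
  m <- matrix(toupper(unclass(aln)) %in% MISSING_CHARS,
              nrow = nrow(aln), dimnames = dimnames(aln))
  m
}

# sequence strings back from the matrix, preserving row order
aln_strings <- function(aln) {
  if (ncol(aln) == 0) return(stats::setNames(rep("", nrow(aln)), rownames(aln)))
  stats::setNames(apply(unclass(aln), 1, paste, collapse = ""), rownames(aln))
}
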