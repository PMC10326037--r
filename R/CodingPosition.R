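#' CodingPosition: an HGVS c.-style coordinate with intronic offset
#'
#' A position on the coding DNA reference sequence of a transcript.
#' `base` is the 1-based CDS coordinate; `offset` places intronic
#' positions relative to the nearest exon boundary: `0` means exonic,
#' `+k` means k nt into the intron downstream (transcript sense) of the
#' exon ending at `base`, `-k` means k nt upstream of the exon starting
#' at `base`. 5'UTR (negative c.) and 3'UTR (`*`) notation are out of
#' scope; `base` must be >= 1.
#'
#' @slot base integer, 1-based CDS coordinate (>= 1).
#' @slot offset integer, signed intronic offset (0 = exonic).
#'
#' @examples
#' parseCpos("c.531+1482")
#' codingPosition(532)
#' @name CodingPosition-class
#' @aliases CodingPosition
#' @exportClass CodingPosition
setClass("CodingPosition",
  representation(base = "integer", offset = "integer"),
  prototype(base = 1L, offset = 0L)
)

setValidity("CodingPosition", function(object) {
  if (length(object@base) != 1L || length(object@offset) != 1L)
    return("base and offset must be scalars")
  if (is.na(object@base) || object@base < 1L)
    return("base must be a positive integer (UTR notation unsupported)")
  if (is.na(object@offset))
    return("offset must not be NA")
  TRUE
})

#' Construct a CodingPosition
#'
#' @param base 1-based CDS coordinate (positive integer).
#' @param offset signed intronic offset; 0 for exonic positions.
#' @return A [CodingPosition-class] object.
#' @export
codingPosition <- function(base, offset = 0L) {
  new("CodingPosition", base = as.integer(base), offset = as.integer(offset))
}

setMethod("show", "CodingPosition", function(object) {
  cat("CodingPosition ", formatCpos(object), "\n", sep = "")
})

#' Parse an HGVS coding-position string
#'
#' Accepts `c.<base>` and `c.<base>[+-]<offset>` with optional internal
#' whitespace (the published form "c.531 + 1482" is tolerated). A zero
#' base or an explicit zero offset is rejected.
#'
#' @param text a single HGVS coding-position string, e.g. `"c.531+1482"`.
#' @return A [CodingPosition-class].
#' @examples
#' parseCpos("c.531+1482")   # base 531, offset +1482
#' parseCpos("c.101-50")     # base 101, offset -50
#' @export
parseCpos <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("[[:space:]]+", "", text)
  m <- regmatches(s, regexec("^c\\.([0-9]+)(([+-])([0-9]+))?$", s))[[1]]
  if (length(m) == 0L)
    stop("malformed coding position: '", text, "'")
  base <- suppressWarnings(as.integer(m[2]))
  if (is.na(base) || base == 0L)
    stop("invalid base '", m[2], "' in coding position '", text, "'")
  offset <- 0L
  if (nzchar(m[3])) {
    k <- suppressWarnings(as.integer(m[5]))
    if (is.na(k) || k == 0L)
      stop("invalid offset '", m[5], "' in coding position '", text, "'")
    offset <- if (m[4] == "-") -k else k
  }
  codingPosition(base, offset)
}

#' Format a CodingPosition as a canonical HGVS string
#'
#' @param p a [CodingPosition-class].
#' @param prefix coordinate-type prefix, `"c."` by default (use `""`
#'   inside composite r. descriptions).
#' @return Canonical string without whitespace, e.g. `"c.531+1482"`.
#' @export
formatCpos <- function(p, prefix = "c.") {
  stopifnot(is(p, "CodingPosition"))
  off <- if (p@offset > 0L) paste0("+", p@offset)
         else if (p@offset < 0L) as.character(p@offset)
         else ""
  paste0(prefix, p@base, off)
}

#' Codon index of an exonic coding position
#'
#' The 1-based index of the codon containing CDS base `base`, i.e.
#' `ceiling(base / 3)`. Intronic positions have no codon and error.
#'
#' @param p a [CodingPosition-class] with `offset == 0`.
#' @return Positive integer codon index.
#' @examples
#' codonIndex(codingPosition(532))  # 178
#' @export
codonIndex <- function(p) {
  stopifnot(is(p, "CodingPosition"))
  if (p@offset != 0L)
    stop("codonIndex is undefined for intronic positions (offset ",
         p@offset, ")")
  as.integer(ceiling(p@base / 3))
}
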