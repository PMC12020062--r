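#' Default label-harmonization dictionary
#'
#' Inconsistent naming of cell lines and endpoints across files (e.g.
#' "HepG2", "HEPG2", "HEP-G2") is a common blocker for automated metadata
#' annotation. Harmonization maps any case/punctuation variant of a known
#' synonym to one canonical label; unknown labels pass through unchanged.
#'
#' @return A named character vector: names are normalized synonym keys
#'   (lower case, alphanumeric only), values are canonical labels.
#' @seealso [canonical_label()]
#' @export
default_harmonization <- function() {
  canon <- list(
    # cell lines
    "BEAS-2B" = c("beas2b", "beas-2b", "beas 2b"),
    "HepG2"   = c("hepg2", "hep-g2", "hep g2"),
    "A549"    = c("a549"),
    "THP-1"   = c("thp1", "thp-1"),
    # endpoints
    "CTG"  = c("ctg", "celltiterglo", "celltiter-glo", "cell titer glo"),
    "DAPI" = c("dapi"),
    "CASP" = c("casp", "casp3", "caspase", "caspase3", "caspase-3",
               "caspglo", "casp-glo"),
    "H2AX" = c("h2ax", "gh2ax", "gammah2ax", "yh2ax", "ph2ax"),
    "8OHG" = c("8ohg", "ohg8", "8-ohg")
  )
  out <- character(0)
  for (label in names(canon)) {
    keys <- vapply(canon[[label]], .harmonize_key, character(1))
    out[keys] <- label
    out[.harmonize_key(label)] <- label
  }
  out
}

.harmonize_key <- function(x) {
  gsub("[^a-z0-9]", "", tolower(x))
}

#' Canonicalize a label against a harmonization dictionary
#'
#' Matching ignores case and punctuation, so canonicalization is idempotent.
#' Labels with no dictionary entry are returned unchanged (trimmed).
#'
#' @param x Character vector of labels.
#' @param dictionary Named character vector as produced by
#'   [default_harmonization()]; names are normalized keys, values canonical
#'   labels.
#' @return Character vector of canonical labels, same length as `x`.
#' @examples
#' canonical_label(c("HEPG2", "HEP-G2", "hepg2"))  # all "HepG2"
#' @export
canonical_label <- function(x, dictionary = default_harmonization()) {
  x <- trimws(as.character(x))
  key <- vapply(x, .harmonize_key, character(1), USE.NAMES = FALSE)
  hit <- !is.na(match(key, names(dictionary))) & nzchar(key)
  x[hit] <- unname(dictionary[key[hit]])
  x
}
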