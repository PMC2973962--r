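#' Standard amino-acid and secondary-structure alphabets
#'
#' `AA_STANDARD` holds the 20 standard one-letter amino-acid codes;
#' nonstandard residues are represented as `"X"` throughout the package
#' ('X' never matches during sequence mapping and is excluded from all
#' propensity and accessibility counts). `DSSP_CODES` is the 8-state
#' secondary-structure alphabet with `"-"` standing for "no assignment";
#' `HELICAL_CODES` are the two codes treated as helical (alpha- and
#' 3-10-helix), everything else counting as non-helical.
#'
#' @format Character vectors.
#' @name alphabets
NULL

#' @rdname alphabets
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname alphabets
#' @export
DSSP_CODES <- c("H", "G", "I", "B", "E", "S", "T", "-")

#' @rdname alphabets
#' @export
HELICAL_CODES <- c("H", "G")

#' @rdname alphabets
#' @export
NONHELICAL_CODES <- c("B", "E", "I", "S", "T", "-")

# internal: one string -> character vector of single letters
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]
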