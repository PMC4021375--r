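#' Amino-acid physico-chemical codes
#'
#' Fixed classification of the 20 standard amino acids into small-integer
#' codes for four physico-chemical properties: side-chain volume (1-5),
#' hydrophobicity (0-3), net charge (-1, 0, +1) and polarity (0 = polar,
#' 1 = apolar). These codes are the numeric substrate for all indel
#' property and local-perturbation parameters.
#'
#' @format A data frame with 20 rows (one per amino acid, rownames are the
#'   one-letter codes) and columns `volume`, `hydrophobicity`, `charge`,
#'   `polarity`.
#' @export
aa_property_table <- local({
  tab <- data.frame(
    volume = c(A = 1, C = 2, D = 2, E = 3, F = 5, G = 1, H = 3, I = 4,
               K = 4, L = 4, M = 4, N = 2, P = 2, Q = 3, R = 4, S = 1,
               T = 2, V = 3, W = 5, Y = 5),
    hydrophobicity = c(A = 2, C = 2, D = 0, E = 0, F = 3, G = 1, H = 1,
                       I = 3, K = 0, L = 3, M = 3, N = 0, P = 0, Q = 1,
                       R = 0, S = 1, T = 1, V = 3, W = 3, Y = 2),
    charge = c(A = 0, C = 0, D = -1, E = -1, F = 0, G = 0, H = 1, I = 0,
               K = 1, L = 0, M = 0, N = 0, P = 0, Q = 0, R = 1, S = 0,
               T = 0, V = 0, W = 0, Y = 0),
    polarity = c(A = 1, C = 1, D = 0, E = 0, F = 1, G = 1, H = 0, I = 1,
                 K = 0, L = 1, M = 1, N = 0, P = 1, Q = 0, R = 0, S = 0,
                 T = 0, V = 1, W = 0, Y = 0)
  )
  tab[order(rownames(tab)), , drop = FALSE]
})

#' @rdname aa_semantic_scales
#' @export
indel_properties <- c("volume", "hydrophobicity", "polarity", "charge")

#' Semantic scales for the physico-chemical properties
#'
#' Ordered mapping from numeric property codes to the semantic labels used
#' in the categorical feature vectors. Volume labels are assigned by rank of
#' the per-residue codes (lowest code = `very_small`); hydrophobicity runs
#' `hydrophilic` to `very_hydrophobic`; polarity is `polar`/`apolar`;
#' charge is `negative`/`neutral`/`positive`.
#'
#' @format A named list, one element per property; each element is a named
#'   character vector mapping code (as name) to semantic label.
#' @export
aa_semantic_scales <- list(
  volume = c(`1` = "very_small", `2` = "small", `3` = "medium",
             `4` = "large", `5` = "very_large"),
  hydrophobicity = c(`0` = "hydrophilic", `1` = "neutral",
                     `2` = "hydrophobic", `3` = "very_hydrophobic"),
  polarity = c(`0` = "polar", `1` = "apolar"),
  charge = c(`-1` = "negative", `0` = "neutral", `1` = "positive")
)

standard_aa <- rownames(aa_property_table)

#' Physico-chemical codes of one amino acid
#'
#' @param residue single upper-case one-letter amino-acid code.
#' @return Named numeric vector with elements `volume`, `hydrophobicity`,
#'   `charge`, `polarity`.
#' @examples
#' aa_properties("A")  # volume 1, hydrophobicity 2, charge 0, polarity 1
#' @export
aa_properties <- function(residue) {
  if (!is.character(residue) || length(residue) != 1L ||
      !residue %in% standard_aa) {
    stop("unknown amino acid: ", deparse(residue), call. = FALSE)
  }
  unlist(aa_property_table[residue, c("volume", "hydrophobicity",
                                      "charge", "polarity")])
}

validate_residues <- function(residues, what = "residues") {
  if (!is.character(residues) || length(residues) != 1L || !nzchar(residues)) {
    stop(what, " must be a non-empty string", call. = FALSE)
  }
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% standard_aa)
  if (length(bad)) {
    stop("non-standard residue '", chars[bad[1]], "' at position ", bad[1],
         " in ", what, " '", residues, "'", call. = FALSE)
  }
  chars
}

#' Numeric property summary of an indel's residues
#'
#' The total is the sum of the per-residue codes; the average is the total
#' divided by the number of residues.
#'
#' @param residues string of one-letter amino-acid codes.
#' @param property one of `"volume"`, `"hydrophobicity"`, `"polarity"`,
#'   `"charge"`.
#' @param mode `"average"` or `"total"`.
#' @return A single numeric value.
#' @examples
#' indel_numeric("AG", "volume", "total")    # 2
#' indel_numeric("AG", "volume", "average")  # 1
#' @export
indel_numeric <- function(residues, property, mode = c("average", "total")) {
  mode <- match.arg(mode)
  property <- match.arg(property, indel_properties)
  chars <- validate_residues(residues)
  total <- sum(aa_property_table[chars, property])
  if (mode == "total") total else total / length(chars)
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Map a numeric property value to its semantic label
#'
#' Averages are rounded half away from zero to the nearest code and looked
#' up on the property's semantic scale. Totals are first divided by the
#' indel length so that they live on the same per-residue code scale, then
#' mapped identically. Values falling outside the scale after rounding are
#' clamped to the nearest end with a warning.
#'
#' @param value numeric value produced by [indel_numeric()].
#' @param property property name.
#' @param mode `"average"` or `"total"`.
#' @param n_residues indel length; required when `mode = "total"`.
#' @return Semantic label (character scalar).
#' @examples
#' to_semantic(1, "volume", "average")             # "very_small"
#' to_semantic(6, "volume", "total", n_residues = 2)  # code 3 -> "medium"
#' @export
to_semantic <- function(value, property, mode = c("average", "total"),
                        n_residues = NULL) {
  mode <- match.arg(mode)
  property <- match.arg(property, indel_properties)
  if (mode == "total") {
    if (is.null(n_residues)) {
      stop("n_residues is required to map a total onto the code scale",
           call. = FALSE)
    }
    value <- value / n_residues
  }
  scale <- aa_semantic_scales[[property]]
  codes <- as.numeric(names(scale))
  code <- round_half_away(value)
  if (code < min(codes) || code > max(codes)) {
    warning("property code ", code, " outside the ", property,
            " scale; clamped", call. = FALSE)
    code <- max(min(code, max(codes)), min(codes))
  }
  unname(scale[as.character(code)])
}
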