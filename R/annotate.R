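perturbation_labels <- c("two_less", "one_less", "equal", "one_more",
                         "two_more")
annotation_scopes <- c("site", "environment", "region")

#' The full categorical parameter schema
#'
#' Returns the ordered list of annotation parameters and their allowed
#' values: conservation and functional-site flags, the semantic
#' physico-chemical summaries of the indel residues (average and total for
#' volume, hydrophobicity, polarity, charge), the five-level local
#' perturbation labels for each scope (site, environment, region) and mode,
#' the structural bins (disorder probability, solvent accessibility,
#' secondary structure), the relative indel position, indel length, and the
#' proline/glycine flags. 45 parameters in total.
#'
#' @return Named list mapping parameter name to its allowed values.
#' @export
feature_schema <- function() {
  bool <- c("false", "true")
  sc <- list(
    conserved_residue = bool, block = bool, pfam = bool, prosite = bool,
    uniprot_domain = bool, macsims_domain = bool
  )
  for (m in c("average", "total")) {
    for (p in indel_properties) {
      sc[[paste("indel", p, m, sep = "_")]] <-
        unname(aa_semantic_scales[[p]])
    }
  }
  for (m in c("average", "total")) {
    for (s in annotation_scopes) {
      for (p in indel_properties) {
        sc[[paste("local_perturbation", s, p, m, sep = "_")]] <-
          perturbation_labels
      }
    }
  }
  sc$probability_of_disorder <- c("structured", "semi_disorder", "disorder")
  sc$rsa <- c("fully_buried", "buried", "intermediate", "exposed",
              "fully_exposed")
  sc$secondary_structure <- c("coil", "helix", "strand", "two")
  sc$relative_indel_position <- c("n_terminal", "middle", "c_terminal")
  sc$indel_length <- c("one", "more_than_one")
  sc$has_proline <- bool
  sc$has_glycine <- bool
  sc
}

as_flag <- function(x) if (isTRUE(x)) "true" else "false"

#' Local sequence scopes of an indel
#'
#' Extracts, from the reference sequence, the three residue strings against
#' which the indel's physico-chemical properties are compared. The *site*
#' is the n residues that take the place of a deletion (the residues
#' immediately downstream of the deleted span, falling back to the upstream
#' residues at the C-terminus) or the n original residues at the position
#' of an insertion. The *environment* is the n residues flanking the indel
#' span on each side; the *region* is 2n flanking residues per side. All
#' scopes are truncated at the protein termini.
#'
#' @param variant an [indel_variant()].
#' @param context its [protein_context()].
#' @return List with `site`, `environment`, `region` (strings) and
#'   `site_positions` (the 1-based reference positions of the site, used to
#'   aggregate per-residue tracks and test interval overlap).
#' @export
local_sequences <- function(variant, context) {
  validate_variant(variant, context)
  L <- nchar(context$sequence)
  n <- nchar(variant$residues)
  p <- variant$position
  if (variant$kind == "deletion") {
    span <- c(p, p + n - 1L)           # the deleted residues
    site_pos <- seq.int(span[2] + 1L, length.out = n)
  } else {
    span <- c(p, p - 1L)               # zero-width: insertion between p-1, p
    site_pos <- seq.int(p, length.out = n)
  }
  site_pos <- site_pos[site_pos >= 1L & site_pos <= L]
  if (!length(site_pos)) {             # indel at the extreme terminus
    site_pos <- seq.int(span[1] - n, length.out = n)
    site_pos <- site_pos[site_pos >= 1L & site_pos <= L]
  }
  if (!length(site_pos)) {
    stop("cannot determine a site for ", variant$protein_id, ":",
         variant$position, ": no flanking residues on either side",
         call. = FALSE)
  }
  flank <- function(width) {
    left <- seq.int(span[1] - width, span[1] - 1L)
    right <- seq.int(span[2] + 1L, span[2] + width)
    keep <- function(v) v[v >= 1L & v <= L]
    c(keep(left), keep(right))
  }
  chars <- strsplit(context$sequence, "", fixed = TRUE)[[1]]
  list(
    site = paste(chars[site_pos], collapse = ""),
    environment = paste(chars[flank(n)], collapse = ""),
    region = paste(chars[flank(2L * n)], collapse = ""),
    site_positions = site_pos
  )
}

# five-level ordinal category of a numeric perturbation
perturbation_category <- function(d) {
  code <- max(min(round_half_away(d), 2), -2)
  perturbation_labels[code + 3L]
}

#' Local physico-chemical perturbation of an indel
#'
#' Computes the difference between a property summary of the local scope
#' and the same summary of the indel residues
#' (scope minus indel, so a negative value means the indel residues carry
#' the larger property value), and bins it into five ordinal labels
#' (`two_less` ... `two_more`, rounding half away from zero and clamping at
#' +/-2).
#'
#' @inheritParams local_sequences
#' @param scope `"site"`, `"environment"` or `"region"`.
#' @param property property name.
#' @param mode `"average"` or `"total"`.
#' @return List with the numeric difference `d` and the `category` label.
#' @export
perturbation <- function(variant, context, scope = annotation_scopes,
                         property = indel_properties,
                         mode = c("average", "total")) {
  scope <- match.arg(scope)
  property <- match.arg(property)
  mode <- match.arg(mode)
  scopes <- local_sequences(variant, context)
  scope_str <- scopes[[scope]]
  if (!nzchar(scope_str)) {
    # a bare scope (single-residue protein) perturbs nothing measurable
    return(list(d = 0, category = "equal"))
  }
  d <- indel_numeric(scope_str, property, mode) -
    indel_numeric(variant$residues, property, mode)
  list(d = d, category = perturbation_category(d))
}

#' Structural category of the indel site: disorder
#'
#' The mean disorder probability P over the site residues is binned as
#' structured (P < 0.4), semi-disorder (0.4 <= P <= 0.7) or
#' disorder (P > 0.7).
#' @inheritParams local_sequences
#' @export
disorder_category <- function(variant, context) {
  p <- mean(context$disorder[local_sequences(variant, context)$site_positions])
  if (p < 0.4) "structured" else if (p <= 0.7) "semi_disorder" else "disorder"
}

#' Structural category of the indel site: solvent accessibility
#'
#' The mean accessibility value over the site residues is binned at 30, 60,
#' 90 and 120 (left-closed bins) into fully_buried, buried, intermediate,
#' exposed, fully_exposed.
#' @inheritParams local_sequences
#' @export
rsa_category <- function(variant, context) {
  r <- mean(context$rsa[local_sequences(variant, context)$site_positions])
  c("fully_buried", "buried", "intermediate", "exposed", "fully_exposed")[
    findInterval(r, c(30, 60, 90, 120)) + 1L]
}

#' Structural category of the indel site: secondary structure
#'
#' Considers the secondary-structure states over the site residues plus one
#' residue of context on each side. An all-coil window is `coil`; a window
#' mixing coil with exactly one non-coil state marks a transition zone and
#' is `two`; otherwise the majority non-coil state wins, ties broken toward
#' `strand` (strand disruptions being the more drastic event).
#' @inheritParams local_sequences
#' @export
ss_category <- function(variant, context) {
  site <- local_sequences(variant, context)$site_positions
  L <- nchar(context$sequence)
  window <- seq.int(max(min(site) - 1L, 1L), min(max(site) + 1L, L))
  states <- context$secondary_structure[window]
  non_coil <- states[states != "coil"]
  if (!length(non_coil)) return("coil")
  if (any(states == "coil") && length(unique(non_coil)) == 1L) return("two")
  counts <- table(non_coil)
  if (length(counts) > 1L && counts[["strand"]] >= counts[["helix"]]) {
    "strand"
  } else {
    names(which.max(counts))
  }
}

#' Relative indel position
#'
#' Ratio between the indel position (midpoint of the deleted span, or the
#' insertion point) and the protein length; the first 10% of the protein is
#' `n_terminal`, the last 10% `c_terminal`, anything else `middle`.
#' @inheritParams local_sequences
#' @export
rip_category <- function(variant, context) {
  n <- nchar(variant$residues)
  mid <- if (variant$kind == "deletion") {
    variant$position + (n - 1) / 2
  } else {
    variant$position - 0.5
  }
  r <- mid / nchar(context$sequence)
  if (r <= 0.10) "n_terminal" else if (r >= 0.90) "c_terminal" else "middle"
}

#' Indel length category and proline/glycine content
#'
#' @param variant an [indel_variant()].
#' @return `length_category`: `"one"` or `"more_than_one"`;
#'   `pro_gly_flags`: named flags `has_proline`, `has_glycine`.
#' @export
length_category <- function(variant) {
  if (nchar(variant$residues) == 1L) "one" else "more_than_one"
}

#' @rdname length_category
#' @export
pro_gly_flags <- function(variant) {
  c(has_proline = as_flag(grepl("P", variant$residues, fixed = TRUE)),
    has_glycine = as_flag(grepl("G", variant$residues, fixed = TRUE)))
}

#' Conservation and functional-site overlap flags
#'
#' A flag is true iff the indel's site span intersects at least one
#' interval of the class (closed-interval intersection), or — for
#' `conserved_residue` — iff any site residue carries the conserved flag.
#' @inheritParams local_sequences
#' @return Named character vector of `"true"`/`"false"` flags for
#'   `conserved_residue`, `block`, `pfam`, `prosite`, `uniprot_domain`,
#'   `macsims_domain`.
#' @export
overlap_flags <- function(variant, context) {
  site <- local_sequences(variant, context)$site_positions
  lo <- min(site); hi <- max(site)
  flags <- c(conserved_residue =
               as_flag(any(context$conserved_residue[site])))
  for (cls in interval_classes) {
    iv <- context$intervals[[cls]]
    hit <- nrow(iv) > 0L && any(iv[, 1] <= hi & iv[, 2] >= lo)
    flags[[cls]] <- as_flag(hit)
  }
  flags
}

#' Annotate one indel with the full categorical parameter set
#'
#' Assembles every parameter of [feature_schema()] for a variant from its
#' protein context. The result is deterministic and independent of any
#' other variant.
#'
#' @inheritParams local_sequences
#' @return Named character vector: one value per schema parameter.
#' @export
annotate_variant <- function(variant, context) {
  schema <- feature_schema()
  out <- character(0)
  tryCatch({
    out <- overlap_flags(variant, context)
    n <- nchar(variant$residues)
    for (m in c("average", "total")) {
      for (p in indel_properties) {
        v <- indel_numeric(variant$residues, p, m)
        out[[paste("indel", p, m, sep = "_")]] <-
          to_semantic(v, p, m, n_residues = n)
      }
    }
    for (m in c("average", "total")) {
      for (s in annotation_scopes) {
        for (p in indel_properties) {
          out[[paste("local_perturbation", s, p, m, sep = "_")]] <-
            perturbation(variant, context, s, p, m)$category
        }
      }
    }
    out[["probability_of_disorder"]] <- disorder_category(variant, context)
    out[["rsa"]] <- rsa_category(variant, context)
    out[["secondary_structure"]] <- ss_category(variant, context)
    out[["relative_indel_position"]] <- rip_category(variant, context)
    out[["indel_length"]] <- length_category(variant)
    out <- c(out, pro_gly_flags(variant))
  }, error = function(e) {
    stop("annotation of ", variant$protein_id, ":", variant$position, " (",
         variant$kind, " '", variant$residues, "') failed: ",
         conditionMessage(e), call. = FALSE)
  })
  out[names(schema)]
}

#' Annotate a cohort of indels
#'
#' @param variants list of [indel_variant()] objects.
#' @param contexts named list of [protein_context()] objects, indexed by
#'   protein id.
#' @return Data frame with columns `variant_id`, `label` and one column per
#'   schema parameter. Convert to a learnable dataset (dropping
#'   `unknown`-labelled records) with [as_dataset()].
#' @export
annotate_all <- function(variants, contexts) {
  stopifnot(length(variants) > 0L)
  rows <- lapply(variants, function(v) {
    ctx <- contexts[[v$protein_id]]
    if (is.null(ctx)) {
      stop("no protein context for '", v$protein_id, "'", call. = FALSE)
    }
    annotate_variant(v, ctx)
  })
  features <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  ids <- vapply(variants, function(v) {
    paste(v$protein_id, v$position, v$kind, v$residues, sep = "_")
  }, "")
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "#")
  cbind(variant_id = ids,
        label = vapply(variants, `[[`, "", "label"),
        features, stringsAsFactors = FALSE)
}

#' Build a learnable dataset from an annotation table
#'
#' Drops records labelled `unknown` (a two-class dataset is required for
#' learning) and attaches the full parameter schema.
#'
#' @param table data frame as returned by [annotate_all()] or
#'   [read_feature_table()].
#' @param schema named list of allowed values; defaults to
#'   [feature_schema()] when the table has exactly those columns, otherwise
#'   to the observed values.
#' @return An [indel_dataset()].
#' @export
as_dataset <- function(table, schema = NULL) {
  stopifnot(all(c("variant_id", "label") %in% names(table)))
  keep <- table$label != "unknown"
  table <- table[keep, , drop = FALSE]
  if (!nrow(table)) stop("no labelled records", call. = FALSE)
  params <- setdiff(names(table), c("variant_id", "label"))
  if (is.null(schema)) {
    full <- feature_schema()
    schema <- if (setequal(params, names(full))) full[params] else NULL
  }
  indel_dataset(table[, params, drop = FALSE], table$label,
                schema = schema, variant_ids = table$variant_id)
}
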