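interval_classes <- c("block", "pfam", "prosite", "uniprot_domain",
                      "macsims_domain")

#' Construct an NFS-Indel variant record
#'
#' A non-frameshifting indel adds or removes whole amino acids from a
#' protein. Coordinates are 1-based: a deletion removes the residues at
#' `position .. position + nchar(residues) - 1`, which must match the
#' reference; an insertion places `residues` immediately before the residue
#' at `position` (so `position` may be `protein length + 1` for a
#' C-terminal extension). Indels longer than 6 amino acids (18 coding base
#' pairs) are rejected.
#'
#' @param protein_id protein identifier (must match a [protein_context()]).
#' @param position 1-based position (see Details above).
#' @param kind `"insertion"` or `"deletion"`.
#' @param residues inserted or deleted amino acids, one-letter codes.
#' @param label `"deleterious"`, `"neutral"` or `"unknown"`.
#' @return An object of class `indel_variant`.
#' @export
indel_variant <- function(protein_id, position, kind, residues,
                          label = "unknown") {
  kind <- match.arg(kind, c("insertion", "deletion"))
  label <- match.arg(label, c("deleterious", "neutral", "unknown"))
  chars <- validate_residues(residues)
  if (length(chars) > 6L) {
    stop("indel '", residues, "' is ", length(chars), " aa long; only ",
         "NFS-Indels of 1-6 aa (3-18 coding base pairs) are supported",
         call. = FALSE)
  }
  position <- as.integer(position)
  if (is.na(position) || position < 1L) {
    stop("position must be a positive integer", call. = FALSE)
  }
  structure(
    list(protein_id = as.character(protein_id), position = position,
         kind = kind, residues = toupper(residues), label = label),
    class = "indel_variant"
  )
}

#' @export
print.indel_variant <- function(x, ...) {
  cat(sprintf("<indel_variant> %s %s of '%s' at %d [%s]\n", x$protein_id,
              x$kind, x$residues, x$position, x$label))
  invisible(x)
}

# check a variant against its protein context; returns the variant
validate_variant <- function(variant, context) {
  L <- nchar(context$sequence)
  n <- nchar(variant$residues)
  if (variant$kind == "deletion") {
    if (variant$position + n - 1L > L) {
      stop("deletion at ", variant$position, " of length ", n,
           " extends past the end of ", variant$protein_id,
           " (length ", L, ")", call. = FALSE)
    }
    ref <- substr(context$sequence, variant$position,
                  variant$position + n - 1L)
    if (ref != variant$residues) {
      stop("reference mismatch for deletion at ", variant$position, " of ",
           variant$protein_id, ": variant says '", variant$residues,
           "', sequence has '", ref, "'", call. = FALSE)
    }
  } else if (variant$position > L + 1L) {
    stop("insertion position ", variant$position, " beyond length + 1 of ",
         variant$protein_id, " (length ", L, ")", call. = FALSE)
  }
  variant
}

#' Construct a protein annotation context
#'
#' Bundles a protein sequence with the per-residue tracks and annotated
#' intervals required to annotate its indels: a disorder probability track
#' (in \[0, 1\]), a solvent-accessibility value track (non-negative),
#' a secondary-structure track (`helix`/`strand`/`coil`), a conserved-residue
#' flag track, and lists of closed 1-based intervals for conserved core
#' blocks and Pfam/Prosite/UniProt/alignment-derived domains.
#'
#' @param protein_id identifier.
#' @param sequence amino-acid string (standard 20-letter alphabet).
#' @param disorder,rsa numeric tracks, one value per residue.
#' @param secondary_structure character track of `helix`, `strand`, `coil`.
#' @param conserved_residue logical track.
#' @param intervals named list with elements `block`, `pfam`, `prosite`,
#'   `uniprot_domain`, `macsims_domain`; each a two-column matrix or data
#'   frame of (start, end) closed intervals, or `NULL` for none.
#' @return An object of class `protein_context`.
#' @export
protein_context <- function(protein_id, sequence,
                            disorder = NULL, rsa = NULL,
                            secondary_structure = NULL,
                            conserved_residue = NULL,
                            intervals = list()) {
  validate_residues(sequence, what = paste0("sequence of ", protein_id))
  L <- nchar(sequence)
  if (is.null(disorder)) disorder <- rep(0, L)
  if (is.null(rsa)) rsa <- rep(0, L)
  if (is.null(secondary_structure)) secondary_structure <- rep("coil", L)
  if (is.null(conserved_residue)) conserved_residue <- rep(FALSE, L)
  for (nm in c("disorder", "rsa", "secondary_structure", "conserved_residue")) {
    track <- get(nm)
    if (length(track) != L) {
      stop("track '", nm, "' of ", protein_id, " has ", length(track),
           " entries but the sequence has ", L, " residues", call. = FALSE)
    }
  }
  if (any(disorder < 0 | disorder > 1)) {
    stop("disorder probabilities of ", protein_id, " must lie in [0, 1]",
         call. = FALSE)
  }
  if (any(rsa < 0)) {
    stop("rsa values of ", protein_id, " must be non-negative", call. = FALSE)
  }
  if (!all(secondary_structure %in% c("helix", "strand", "coil"))) {
    stop("secondary structure states must be helix/strand/coil", call. = FALSE)
  }
  iv <- stats::setNames(vector("list", length(interval_classes)),
                        interval_classes)
  for (cls in names(intervals)) {
    if (!cls %in% interval_classes) {
      stop("unknown interval class '", cls, "'", call. = FALSE)
    }
    m <- as.matrix(intervals[[cls]])
    if (length(m)) {
      storage.mode(m) <- "integer"
      if (ncol(m) != 2L || any(m[, 1] < 1L) || any(m[, 2] > L) ||
          any(m[, 1] > m[, 2])) {
        stop(cls, " interval out of bounds for ", protein_id,
             " (length ", L, ")", call. = FALSE)
      }
      iv[[cls]] <- m
    }
  }
  for (cls in interval_classes) {
    if (is.null(iv[[cls]])) iv[[cls]] <- matrix(integer(), ncol = 2L)
  }
  structure(
    list(protein_id = as.character(protein_id), sequence = toupper(sequence),
         disorder = as.numeric(disorder), rsa = as.numeric(rsa),
         secondary_structure = as.character(secondary_structure),
         conserved_residue = as.logical(conserved_residue),
         intervals = iv),
    class = "protein_context"
  )
}

#' @export
print.protein_context <- function(x, ...) {
  cat(sprintf("<protein_context> %s, %d aa, %d annotated intervals\n",
              x$protein_id, nchar(x$sequence),
              sum(vapply(x$intervals, nrow, 0L))))
  invisible(x)
}

#' Run configuration
#'
#' Collects the tunable parameters shared by feature selection, rule
#' learning and cross-validation. `minpos` is the minimum number of
#' positive (deleterious) training examples a rule must cover; `noise` the
#' maximum number of negatives it may cover (0 forbids false positives on
#' the training set). `correlation_cutoff` and `x_cutoff` drive parameter
#' selection; `beam_width` and `max_literals` bound the rule search.
#'
#' @param minpos minimum positives per rule (default 6).
#' @param noise maximum negatives per rule (default 0).
#' @param correlation_cutoff association cutoff in \[0, 1\] (default 0.7).
#' @param x_cutoff discriminative-power cutoff (default 0.2).
#' @param folds number of cross-validation folds (default 10).
#' @param seed integer seed; mandatory for any stochastic operation.
#' @param beam_width beam width of the rule search (default 5).
#' @param max_literals maximum literals per rule (default 6).
#' @return An object of class `run_config`.
#' @export
run_config <- function(minpos = 6L, noise = 0L, correlation_cutoff = 0.7,
                       x_cutoff = 0.2, folds = 10L, seed = NULL,
                       beam_width = 5L, max_literals = 6L) {
  stopifnot(minpos >= 1L, noise >= 0L,
            correlation_cutoff >= 0, correlation_cutoff <= 1,
            x_cutoff >= 0, folds >= 2L, beam_width >= 1L, max_literals >= 1L)
  structure(
    list(minpos = as.integer(minpos), noise = as.integer(noise),
         correlation_cutoff = correlation_cutoff, x_cutoff = x_cutoff,
         folds = as.integer(folds),
         seed = if (is.null(seed)) NULL else as.integer(seed),
         beam_width = as.integer(beam_width),
         max_literals = as.integer(max_literals)),
    class = "run_config"
  )
}

require_seed <- function(config) {
  if (is.null(config$seed)) {
    stop("a seed is mandatory for stochastic operations; set run_config(seed=)",
         call. = FALSE)
  }
  config$seed
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level keys are [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    stop("unknown configuration key(s) in ", path, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  do.call(run_config, vals)
}

#' Construct a labelled categorical dataset
#'
#' The container consumed by feature selection and rule learning: one row
#' per variant, one categorical column per annotation parameter, plus a
#' two-class label. Records labelled `unknown` are not admitted.
#'
#' @param features data frame of categorical (character) columns.
#' @param labels character vector, `"deleterious"` or `"neutral"`.
#' @param schema named list mapping each parameter to its allowed values;
#'   defaults to the observed values of each column.
#' @param variant_ids optional record identifiers (default `v1`, `v2`, ...).
#' @return An object of class `indel_dataset`.
#' @export
indel_dataset <- function(features, labels, schema = NULL,
                          variant_ids = NULL) {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  features[] <- lapply(features, as.character)
  if (nrow(features) != length(labels)) {
    stop("features and labels disagree on the number of records",
         call. = FALSE)
  }
  if (!all(labels %in% c("deleterious", "neutral"))) {
    stop("labels must be 'deleterious' or 'neutral'", call. = FALSE)
  }
  if (is.null(schema)) {
    schema <- lapply(features, function(col) sort(unique(col)))
  }
  if (!setequal(names(schema), names(features))) {
    stop("schema parameters do not match feature columns", call. = FALSE)
  }
  features <- features[, names(schema), drop = FALSE]
  for (p in names(schema)) {
    bad <- setdiff(unique(features[[p]]), schema[[p]])
    if (length(bad)) {
      stop("value '", bad[1], "' of parameter '", p,
           "' is not in the schema", call. = FALSE)
    }
  }
  if (is.null(variant_ids)) {
    variant_ids <- paste0("v", seq_len(nrow(features)))
  }
  if (anyDuplicated(variant_ids)) {
    stop("variant ids must be unique", call. = FALSE)
  }
  structure(
    list(features = features, labels = as.character(labels),
         schema = schema, variant_ids = as.character(variant_ids)),
    class = "indel_dataset"
  )
}

#' @export
print.indel_dataset <- function(x, ...) {
  cat(sprintf(
    "<indel_dataset> %d records (%d deleterious / %d neutral), %d parameters\n",
    nrow(x$features), sum(x$labels == "deleterious"),
    sum(x$labels == "neutral"), length(x$schema)))
  invisible(x)
}

# row subset preserving schema
subset_dataset <- function(dataset, idx) {
  indel_dataset(dataset$features[idx, , drop = FALSE],
                dataset$labels[idx], schema = dataset$schema,
                variant_ids = dataset$variant_ids[idx])
}

# column subset (parameter selection)
subset_parameters <- function(dataset, parameters) {
  stopifnot(all(parameters %in% names(dataset$schema)))
  indel_dataset(dataset$features[, parameters, drop = FALSE],
                dataset$labels, schema = dataset$schema[parameters],
                variant_ids = dataset$variant_ids)
}
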