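#' Specification for a planted-rule synthetic dataset
#'
#' Describes a labelled categorical dataset in which the positive
#' (deleterious) class is generated by a known set of conjunctive rules:
#' negatives are drawn from a background distribution and resampled until
#' they satisfy no planted rule; positives are drawn from the background
#' and then forced to satisfy one planted rule (assigned round-robin) by
#' overwriting that rule's literal parameters. This emulates a labelled
#' annotation table without reference to any real cohort.
#'
#' The default schema has 15 parameters (six binary flags, five
#' three-level factors, four five-level factors) and two planted rules of
#' two and three literals; the background distribution is near-uniform
#' with a mild skew toward each parameter's first value.
#'
#' @param schema named list of allowed values per parameter.
#' @param planted_rules list of named character vectors (parameter ->
#'   value conjunctions).
#' @param n_pos,n_neg class sizes (defaults 200/200).
#' @param label_noise_rate probability in \[0, 1) that a record's label is
#'   flipped after construction (default 0).
#' @param background named list of per-parameter value probabilities;
#'   defaults to the mild-skew background.
#' @return List of class `planted_spec`.
#' @export
planted_spec <- function(schema = NULL, planted_rules = NULL,
                         n_pos = 200L, n_neg = 200L,
                         label_noise_rate = 0, background = NULL) {
  if (is.null(schema)) {
    schema <- c(
      stats::setNames(rep(list(c("false", "true")), 6),
                      sprintf("flag%02d", 1:6)),
      stats::setNames(rep(list(c("low", "mid", "high")), 5),
                      sprintf("tri%02d", 1:5)),
      stats::setNames(rep(list(paste0("v", 1:5)), 4),
                      sprintf("quin%02d", 1:4))
    )
  }
  if (is.null(planted_rules)) {
    planted_rules <- list(
      c(flag01 = "true", tri01 = "high"),
      c(quin01 = "v5", flag02 = "true", tri02 = "low")
    )
  }
  stopifnot(n_pos > 0L, n_neg > 0L,
            label_noise_rate >= 0, label_noise_rate < 1)
  for (r in planted_rules) {
    stopifnot(length(r) >= 1L, !is.null(names(r)))
    for (p in names(r)) {
      if (is.null(schema[[p]]) || !r[[p]] %in% schema[[p]]) {
        stop("planted rule literal ", p, " = ", r[[p]],
             " is unsatisfiable under the schema", call. = FALSE)
      }
    }
  }
  if (is.null(background)) {
    background <- lapply(schema, function(values) {
      w <- seq(1.5, 1, length.out = length(values))
      stats::setNames(w / sum(w), values)
    })
  }
  structure(
    list(schema = schema, planted_rules = planted_rules,
         n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
         label_noise_rate = label_noise_rate, background = background),
    class = "planted_spec"
  )
}

satisfies_any <- function(record, rules) {
  for (r in rules) {
    if (all(record[names(r)] == r)) return(TRUE)
  }
  FALSE
}

#' Generate a labelled dataset with planted rules
#'
#' @param spec a [planted_spec()].
#' @param seed integer seed; the output is a pure function of
#'   `(spec, seed)`.
#' @return List with `dataset` (an [indel_dataset()]) and `ground_truth`
#'   (data frame: variant_id, generating rule index — `NA` for background
#'   negatives —, intended label, final label, flipped flag).
#' @export
generate_dataset <- function(spec, seed) {
  stopifnot(inherits(spec, "planted_spec"))
  set.seed(as.integer(seed))
  params <- names(spec$schema)
  draw_background <- function() {
    vapply(params, function(p) {
      sample(spec$schema[[p]], 1L, prob = spec$background[[p]])
    }, "")
  }
  n <- spec$n_pos + spec$n_neg
  records <- vector("list", n)
  rule_of <- rep(NA_integer_, n)
  intended <- c(rep("deleterious", spec$n_pos), rep("neutral", spec$n_neg))
  for (i in seq_len(spec$n_pos)) {
    rec <- draw_background()
    k <- ((i - 1L) %% length(spec$planted_rules)) + 1L
    rule <- spec$planted_rules[[k]]
    rec[names(rule)] <- rule
    records[[i]] <- rec
    rule_of[i] <- k
  }
  for (i in seq.int(spec$n_pos + 1L, n)) {
    ok <- FALSE
    for (attempt in seq_len(10000L)) {
      rec <- draw_background()
      if (!satisfies_any(rec, spec$planted_rules)) { ok <- TRUE; break }
    }
    if (!ok) {
      stop("background distribution cannot avoid the planted rules ",
           "(rejection probability > 0.999)", call. = FALSE)
    }
    records[[i]] <- rec
  }
  flipped <- if (spec$label_noise_rate > 0) {
    stats::runif(n) < spec$label_noise_rate
  } else {
    rep(FALSE, n)
  }
  final <- ifelse(flipped,
                  ifelse(intended == "deleterious", "neutral",
                         "deleterious"),
                  intended)
  features <- as.data.frame(do.call(rbind, records),
                            stringsAsFactors = FALSE)
  ids <- sprintf("sim%04d", seq_len(n))
  dataset <- indel_dataset(features, final, schema = spec$schema,
                           variant_ids = ids)
  list(dataset = dataset,
       ground_truth = data.frame(
         variant_id = ids, rule = rule_of, intended_label = intended,
         final_label = final, flipped = flipped,
         stringsAsFactors = FALSE))
}

#' Default protein architecture for synthetic contexts
#'
#' Three-domain layout: a disordered exposed N-terminal coil, a structured
#' buried core alternating helices and strands inside a conserved block
#' and a Pfam-style domain, and a semi-disordered C-terminal coil.
#'
#' @param length protein length (>= 30).
#' @return Architecture list understood by [generate_protein_context()]:
#'   `segments` (data frame start, end, ss, disorder, rsa), `intervals`
#'   (named list), `conserved` (positions).
#' @export
default_architecture <- function(length) {
  stopifnot(length >= 30L)
  b <- function(f) max(1L, as.integer(round(f * length)))
  core <- c(b(0.25), b(0.75))
  quarter <- as.integer(round(diff(core) / 4))
  segments <- data.frame(
    start = c(1L, core[1], core[1] + quarter, core[1] + 2L * quarter,
              core[1] + 3L * quarter, core[2] + 1L),
    end = c(core[1] - 1L, core[1] + quarter - 1L,
            core[1] + 2L * quarter - 1L, core[1] + 3L * quarter - 1L,
            core[2], length),
    ss = c("coil", "helix", "strand", "helix", "strand", "coil"),
    disorder = c(0.9, 0.1, 0.1, 0.1, 0.1, 0.55),
    rsa = c(130, 20, 20, 45, 45, 100),
    stringsAsFactors = FALSE
  )
  list(segments = segments,
       intervals = list(block = matrix(core, ncol = 2L),
                        pfam = matrix(core, ncol = 2L)),
       conserved = seq.int(core[1], core[2]))
}

#' Generate a synthetic protein context
#'
#' Builds a random protein sequence with piecewise-constant annotation
#' tracks following an architecture description: per-segment secondary
#' structure, disorder probability and solvent-accessibility level (with
#' small within-segment jitter), plus conserved positions and annotated
#' intervals. Optionally emits validated indel variants positioned to hit
#' requested positions (deletions take their residues from the generated
#' sequence; insertions draw random residues).
#'
#' @param length protein length (>= 30).
#' @param architecture architecture list (see [default_architecture()]);
#'   `NULL` for the default layout.
#' @param seed integer seed; output is a pure function of the arguments.
#' @param protein_id identifier (default `"synthetic1"`).
#' @param variants optional data frame with columns `position`, `kind`,
#'   `length` and optional `label` describing indels to emit.
#' @return List with `context` (a [protein_context()]) and `variants`
#'   (list of [indel_variant()], possibly empty).
#' @export
generate_protein_context <- function(length, architecture = NULL, seed,
                                     protein_id = "synthetic1",
                                     variants = NULL) {
  stopifnot(length >= 30L)
  set.seed(as.integer(seed))
  if (is.null(architecture)) architecture <- default_architecture(length)
  seg <- architecture$segments
  stopifnot(is.data.frame(seg),
            all(c("start", "end", "ss", "disorder", "rsa") %in% names(seg)))
  if (any(seg$end > length) || any(seg$start < 1L)) {
    stop("architecture segments exceed the protein length", call. = FALSE)
  }
  sequence <- paste(sample(standard_aa, length, replace = TRUE),
                    collapse = "")
  disorder <- rep(0.5, length)
  rsa <- rep(50, length)
  ss <- rep("coil", length)
  for (i in seq_len(nrow(seg))) {
    span <- seq.int(seg$start[i], seg$end[i])
    disorder[span] <- pmin(pmax(
      seg$disorder[i] + stats::runif(length(span), -0.03, 0.03), 0), 1)
    rsa[span] <- pmax(seg$rsa[i] + stats::runif(length(span), -4, 4), 0)
    ss[span] <- seg$ss[i]
  }
  conserved <- rep(FALSE, length)
  if (!is.null(architecture$conserved)) {
    conserved[architecture$conserved] <- TRUE
  }
  context <- protein_context(
    protein_id, sequence, disorder = disorder, rsa = rsa,
    secondary_structure = ss, conserved_residue = conserved,
    intervals = architecture$intervals %||% list())
  out_variants <- list()
  if (!is.null(variants)) {
    stopifnot(all(c("position", "kind", "length") %in% names(variants)))
    out_variants <- lapply(seq_len(nrow(variants)), function(i) {
      pos <- as.integer(variants$position[i])
      n <- as.integer(variants$length[i])
      kind <- variants$kind[i]
      residues <- if (kind == "deletion") {
        substr(sequence, pos, pos + n - 1L)
      } else {
        paste(sample(standard_aa, n, replace = TRUE), collapse = "")
      }
      label <- if ("label" %in% names(variants)) {
        variants$label[i]
      } else {
        "unknown"
      }
      validate_variant(indel_variant(protein_id, pos, kind, residues,
                                     label), context)
    })
  }
  list(context = context, variants = out_variants)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
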