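#' Read protein sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] that enforces the
#' package's contract: unique record ids (the first whitespace-delimited
#' token of each header), upper-case sequences, and the 20-letter standard
#' amino-acid alphabet only.
#'
#' @param path FASTA file.
#' @return Named character vector, protein id -> sequence.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (!length(seqs)) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate protein id '", dup[1], "' in ", path, call. = FALSE)
  }
  out <- stats::setNames(toupper(as.character(seqs)), ids)
  for (id in ids) {
    validate_residues(out[[id]], what = paste0("sequence of ", id,
                                               " in ", path))
  }
  out
}

read_tsv_checked <- function(path, required, what) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop(what, " file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab
}

#' Read an NFS-Indel variant table
#'
#' Reads a headered TSV with columns `protein_id`, `position`, `kind`,
#' `residues` and (optionally) `label`, and validates every record against
#' its protein context: deletions must match the reference sequence, and
#' only indels of 1-6 amino acids (3-18 coding base pairs) are admitted.
#'
#' @param path TSV file.
#' @param contexts named list of [protein_context()] objects (or, for
#'   sequence-only validation, a named character vector of sequences).
#' @return List of [indel_variant()] objects.
#' @export
read_variants <- function(path, contexts) {
  tab <- read_tsv_checked(path, c("protein_id", "position", "kind",
                                  "residues"), "variant")
  if (is.character(contexts)) {
    contexts <- lapply(stats::setNames(nm = names(contexts)), function(id) {
      protein_context(id, contexts[[id]])
    })
  }
  if (!"label" %in% names(tab)) tab$label <- "unknown"
  lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    where <- paste0(path, " record ", i)
    if (!row$label %in% c("deleterious", "neutral", "unknown")) {
      stop("unknown label token '", row$label, "' in ", where, call. = FALSE)
    }
    ctx <- contexts[[row$protein_id]]
    if (is.null(ctx)) {
      stop("unknown protein id '", row$protein_id, "' in ", where,
           call. = FALSE)
    }
    v <- tryCatch(
      indel_variant(row$protein_id, row$position, row$kind, row$residues,
                    row$label),
      error = function(e) {
        stop(conditionMessage(e), " (", where, ")", call. = FALSE)
      })
    tryCatch(validate_variant(v, ctx), error = function(e) {
      stop(conditionMessage(e), " (", where, ")", call. = FALSE)
    })
  })
}

#' Read per-residue annotation tracks and interval annotations
#'
#' The track file is a TSV with columns `protein_id`, `index` (1-based
#' residue index), `disorder`, `rsa`, `secondary_structure`,
#' `conserved`; the interval file a TSV with columns `protein_id`,
#' `feature_class` (one of block, pfam, prosite, uniprot_domain,
#' macsims_domain), `start`, `end`. Tracks must cover every residue of
#' each sequence exactly once.
#'
#' @param tracks_path,intervals_path TSV files; `intervals_path` may be
#'   `NULL` if there are no interval annotations.
#' @param sequences named character vector as returned by [read_fasta()].
#' @return Named list of [protein_context()] objects.
#' @export
read_tracks <- function(tracks_path, intervals_path = NULL, sequences) {
  tr <- read_tsv_checked(tracks_path,
                         c("protein_id", "index", "disorder", "rsa",
                           "secondary_structure", "conserved"), "track")
  iv <- if (is.null(intervals_path)) {
    data.frame(protein_id = character(), feature_class = character(),
               start = integer(), end = integer())
  } else {
    read_tsv_checked(intervals_path,
                     c("protein_id", "feature_class", "start", "end"),
                     "interval")
  }
  bad_cls <- setdiff(unique(iv$feature_class), interval_classes)
  if (length(bad_cls)) {
    stop("unknown feature_class '", bad_cls[1], "' in ", intervals_path,
         call. = FALSE)
  }
  lapply(stats::setNames(nm = names(sequences)), function(id) {
    rows <- tr[tr$protein_id == id, , drop = FALSE]
    L <- nchar(sequences[[id]])
    if (nrow(rows) != L ||
        !identical(sort(as.integer(rows$index)), seq_len(L))) {
      stop("track file ", tracks_path, ": protein ", id, " has ",
           nrow(rows), " track rows for ", L, " residues", call. = FALSE)
    }
    rows <- rows[order(rows$index), ]
    ivp <- iv[iv$protein_id == id, , drop = FALSE]
    intervals <- lapply(stats::setNames(nm = interval_classes), function(cls) {
      m <- ivp[ivp$feature_class == cls, c("start", "end"), drop = FALSE]
      as.matrix(m)
    })
    protein_context(id, sequences[[id]],
                    disorder = rows$disorder, rsa = rows$rsa,
                    secondary_structure = rows$secondary_structure,
                    conserved_residue = as.logical(rows$conserved),
                    intervals = intervals)
  })
}

#' Write / read a categorical feature table
#'
#' The on-disk format is a TSV whose header block (comment lines of the
#' form `#param <name> <v1,v2,...>`) enumerates each parameter's allowed
#' values, followed by columns `variant_id`, `label` and one column per
#' parameter. Round-trip identity holds:
#' `read_feature_table(write_feature_table(d, p))` reproduces `d` exactly.
#'
#' @param x an [indel_dataset()], or an annotation data frame from
#'   [annotate_all()] (which may contain `unknown` labels).
#' @param path output TSV.
#' @param schema allowed values per parameter when `x` is a data frame;
#'   defaults to [feature_schema()] if the columns match, otherwise to the
#'   observed values.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns an [indel_dataset()] when every label is
#'   deleterious/neutral, otherwise the annotation data frame with the
#'   schema attached as attribute `"schema"`.
#' @export
write_feature_table <- function(x, path, schema = NULL) {
  if (inherits(x, "indel_dataset")) {
    schema <- x$schema
    tab <- cbind(variant_id = x$variant_ids, label = x$labels, x$features,
                 stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("variant_id", "label") %in% names(x)))
    tab <- x
    params <- setdiff(names(tab), c("variant_id", "label"))
    if (is.null(schema)) {
      full <- feature_schema()
      schema <- if (setequal(params, names(full))) {
        full[params]
      } else {
        lapply(tab[params], function(col) sort(unique(col)))
      }
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (p in names(schema)) {
    writeLines(paste0("#param\t", p, "\t",
                      paste(schema[[p]], collapse = ",")), con)
  }
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#param\t", lines, value = TRUE)
  if (!length(hdr)) {
    stop("feature table ", path, " lacks the #param schema header block",
         call. = FALSE)
  }
  parts <- strsplit(hdr, "\t", fixed = TRUE)
  schema <- stats::setNames(
    lapply(parts, function(p) strsplit(p[3], ",", fixed = TRUE)[[1]]),
    vapply(parts, `[`, "", 2L))
  tab <- read_tsv_checked(path, c("variant_id", "label"), "feature")
  missing <- setdiff(names(schema), names(tab))
  if (length(missing)) {
    stop("feature table ", path, " lacks parameter column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab <- tab[, c("variant_id", "label", names(schema)), drop = FALSE]
  tab[] <- lapply(tab, as.character)
  for (p in names(schema)) {
    bad <- setdiff(unique(tab[[p]]), schema[[p]])
    if (length(bad)) {
      stop("feature table ", path, ", parameter '", p, "': value '",
           bad[1], "' is not in the schema", call. = FALSE)
    }
  }
  bad_lab <- setdiff(unique(tab$label),
                     c("deleterious", "neutral", "unknown"))
  if (length(bad_lab)) {
    stop("feature table ", path, ": unknown label token '", bad_lab[1], "'",
         call. = FALSE)
  }
  if (all(tab$label %in% c("deleterious", "neutral"))) {
    indel_dataset(tab[, names(schema), drop = FALSE], tab$label,
                  schema = schema, variant_ids = tab$variant_id)
  } else {
    structure(tab, schema = schema)
  }
}

#' Write / read a rule set
#'
#' JSON serialisation is lossless (literals, per-rule training statistics,
#' configuration snapshot) and is the only format read back. The text
#' format renders each rule in the human-readable style
#' `deleterious (A) if parameter (A, value), ...` and exists for people,
#' not parsers.
#'
#' @param ruleset a [rule_set] as returned by [learn()].
#' @param path output file.
#' @param format `"json"` or `"text"`.
#' @return `write_rules` returns `path` invisibly; `read_rules` a
#'   [rule_set].
#' @export
write_rules <- function(ruleset, path, format = c("json", "text")) {
  format <- match.arg(format)
  stopifnot(inherits(ruleset, "rule_set"))
  if (format == "text") {
    writeLines(vapply(ruleset$rules, format_rule, ""), path)
    return(invisible(path))
  }
  payload <- list(
    config = ruleset$config[c("minpos", "noise", "beam_width",
                              "max_literals", "seed")],
    schema = ruleset$schema,
    rules = lapply(ruleset$rules, function(r) {
      list(literals = as.list(r$literals),
           train_pos_covered = r$pos_covered,
           train_neg_covered = r$neg_covered,
           seed_example_id = r$seed_example)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path),
                      error = function(e) {
                        stop("malformed rule file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
                      })
  if (!all(c("config", "schema", "rules") %in% names(payload))) {
    stop("malformed rule file ", path,
         ": expected config/schema/rules members", call. = FALSE)
  }
  cfg <- payload$config
  config <- run_config(minpos = cfg$minpos, noise = cfg$noise,
                       seed = cfg$seed, beam_width = cfg$beam_width,
                       max_literals = cfg$max_literals)
  schema <- lapply(payload$schema, function(v) unlist(v, use.names = FALSE))
  rules <- lapply(payload$rules, function(r) {
    new_rule(unlist(r$literals), r$train_pos_covered, r$train_neg_covered,
             r$seed_example_id)
  })
  new_rule_set(rules, schema, config)
}
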