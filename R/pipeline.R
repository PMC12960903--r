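# End-to-end orchestration: configuration handling and the seven-step
# annotation pipeline (parse -> reconstruct -> enumerate/score/select ->
# classify -> project/insert CDS -> uORF/Kozak/NMD/UTR -> outputs).

.CONFIG_DEFAULTS <- list(
  gtf_path = NULL, genome_path = NULL, model = NULL,
  n_top = 5L, coding_cutoff = NULL, uorf_min_prob = NULL,
  nmd_threshold_nt = 50L, min_uorf_length_nt = 9L,
  output_dir = NULL, dialect = "auto", seed = 1L
)

#' Build a validated pipeline configuration
#'
#' @param gtf_path Input GTF/GFF3 path.
#' @param genome_path Genome FASTA path.
#' @param model Model selector: a `coding_model`, a path to a model JSON
#'   written by [save_coding_model()], or the label `"fixture"` for the
#'   deterministic synthetic-trained test model.
#' @param output_dir Directory for all outputs (created if needed).
#' @param n_top Number of ORFs kept per transcript (default 5).
#' @param coding_cutoff Optional cutoff overriding the model's own.
#' @param uorf_min_prob Minimum uORF probability; defaults to the coding
#'   cutoff in use.
#' @param nmd_threshold_nt NMD distance threshold (default 50).
#' @param min_uorf_length_nt Minimum uORF length (default 9).
#' @param dialect `"auto"`, `"gtf"` or `"gff3"`.
#' @param seed Integer seed (affects model training only, never annotation).
#' @return An `orf_config` list.
#' @export
orf_config <- function(gtf_path, genome_path, model, output_dir,
                       n_top = 5L, coding_cutoff = NULL,
                       uorf_min_prob = NULL, nmd_threshold_nt = 50L,
                       min_uorf_length_nt = 9L, dialect = "auto",
                       seed = 1L) {
  cfg <- list(
    gtf_path = gtf_path, genome_path = genome_path, model = model,
    n_top = as.integer(n_top), coding_cutoff = coding_cutoff,
    uorf_min_prob = uorf_min_prob,
    nmd_threshold_nt = as.integer(nmd_threshold_nt),
    min_uorf_length_nt = as.integer(min_uorf_length_nt),
    output_dir = output_dir, dialect = dialect, seed = as.integer(seed)
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  for (req in c("gtf_path", "genome_path", "model", "output_dir")) {
    if (is.null(cfg[[req]])) {
      stop("usage error: required configuration field missing: ", req,
           call. = FALSE)
    }
  }
  if (cfg$n_top < 1) stop("n_top must be >= 1", call. = FALSE)
  for (p in c("coding_cutoff", "uorf_min_prob")) {
    v <- cfg[[p]]
    if (!is.null(v) && (!is.numeric(v) || v < 0 || v > 1)) {
      stop("validation error: ", p, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$nmd_threshold_nt < 0) stop("nmd_threshold_nt must be >= 0",
                                     call. = FALSE)
  if (!cfg$dialect %in% c("auto", "gtf", "gff3")) {
    stop("dialect must be auto, gtf or gff3", call. = FALSE)
  }
  structure(cfg, class = "orf_config")
}

#' Load configuration from a JSON file with overrides
#'
#' Precedence: explicit overrides (e.g. CLI flags) beat file values beat
#' defaults.  Unknown keys in the file produce a warning.
#'
#' @param path Path to a JSON configuration file, or `NULL`.
#' @param overrides Named list of values taking precedence over the file.
#' @return An `orf_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- .CONFIG_DEFAULTS
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    file_cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(file_cfg), names(.CONFIG_DEFAULTS))
    if (length(unknown) > 0) {
      warning("unknown configuration key(s) ignored: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
    cfg <- utils::modifyList(cfg, file_cfg[setdiff(names(file_cfg), unknown)])
  }
  overrides <- overrides[!vapply(overrides, is.null, TRUE)]
  cfg <- utils::modifyList(cfg, overrides)
  cfg$n_top <- as.integer(cfg$n_top)
  cfg$nmd_threshold_nt <- as.integer(cfg$nmd_threshold_nt)
  cfg$min_uorf_length_nt <- as.integer(cfg$min_uorf_length_nt)
  cfg$seed <- as.integer(cfg$seed)
  validate_config(cfg)
}

#' Resolve a model selector to a coding model
#'
#' @param selector A `coding_model`, a model JSON path, or `"fixture"`.
#' @param seed Seed used when the fixture model has to be trained.
#' @return A `coding_model`.
#' @export
resolve_model <- function(selector, seed = 1L) {
  if (inherits(selector, "coding_model")) return(selector)
  if (is.character(selector) && length(selector) == 1) {
    if (identical(selector, "fixture")) {
      return(train_fixture_model(seed = seed))
    }
    if (file.exists(selector)) {
      return(load_coding_model(selector))
    }
    if (selector %in% c("human", "mouse", "fly", "zebrafish")) {
      stop("no bundled model for species '", selector, "': train one with ",
           "train_coding_model() (its recommended cutoff is ",
           species_cutoff(selector), ") and pass the model file",
           call. = FALSE)
    }
  }
  stop("cannot resolve coding model selector", call. = FALSE)
}

#' Run the full annotation pipeline
#'
#' Executes parse, sequence reconstruction, ORF enumeration/scoring/
#' selection, coding classification, exon-aware CDS/UTR insertion, uORF,
#' Kozak, NMD and UTR annotation, then writes the annotated GTF/GFF3, the
#' summary TSV, five FASTA exports and a run log into `output_dir`.
#' Annotation is fully deterministic given the configuration (the seed
#' affects model training only); the data outputs of two identical runs are
#' byte-identical.
#'
#' @param config An `orf_config` from [orf_config()] or [load_config()].
#' @return Invisibly, a list with `summary` (data.frame), `annotations`,
#'   `transcripts` (the parsed `transcript_set`), `files` (output paths)
#'   and `report` (counts).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(unclass(config))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
    log_lines <<- c(log_lines, msg)
  }
  say("orfscribe run started")
  say("config: n_top=", config$n_top,
      " cutoff=", config$coding_cutoff %||% "(model default)",
      " uorf_min_prob=", config$uorf_min_prob %||% "(coding cutoff)",
      " nmd_threshold=", config$nmd_threshold_nt,
      " dialect=", config$dialect, " seed=", config$seed)

  scoring_model <- resolve_model(config$model, seed = config$seed)
  say("step 0: coding model '", scoring_model$species_label,
      "' (cutoff ", config$coding_cutoff %||% scoring_model$cutoff, ")")

  tset <- parse_annotation(config$gtf_path, dialect = config$dialect)
  say("step 1: parsed ", tset$report$n_transcripts, " transcripts (",
      tset$report$n_dropped, " dropped at parse)")
  genome <- open_genome(config$genome_path)

  annotations <- list()
  records <- list()
  n_skipped <- 0L
  for (t in names(tset$models)) {
    model <- tset$models[[t]]
    seq <- withCallingHandlers(
      reconstruct_sequence(model, genome),
      warning = function(w) {
        say("warning: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    if (is.na(seq)) {
      n_skipped <- n_skipped + 1L
      next
    }
    ann <- annotate_transcript(
      model, seq, scoring_model,
      n_top = config$n_top, coding_cutoff = config$coding_cutoff,
      uorf_min_prob = config$uorf_min_prob,
      nmd_threshold = config$nmd_threshold_nt,
      min_uorf_length = config$min_uorf_length_nt
    )
    annotations[[t]] <- ann
    if (ann$coding) {
      records[[t]] <- build_feature_records(model, ann)
    }
  }
  n_coding <- sum(vapply(annotations, function(a) a$coding, TRUE))
  say("steps 2-7: annotated ", length(annotations), " transcripts (",
      n_coding, " coding, ", n_skipped, " skipped: missing contig/bounds)")

  files <- c(
    annotation = file.path(config$output_dir,
                           paste0("annotated.",
                                  if (tset$dialect == "gff3") "gff3" else "gtf")),
    summary = file.path(config$output_dir, "summary.tsv"),
    orfs = file.path(config$output_dir, "orfs_topN.fa"),
    log = file.path(config$output_dir, "run.log")
  )
  write_annotation(tset, records, files[["annotation"]])
  kept_models <- tset$models[names(annotations)]
  summary_df <- summarize_transcripts(kept_models, annotations)
  write_summary(summary_df, files[["summary"]])
  seq_paths <- write_sequence_exports(annotations, config$output_dir)
  write_orf_fasta(annotations, files[["orfs"]])
  files <- c(files, seq_paths)
  say("outputs written to ", config$output_dir)
  say("final counts: parsed=", tset$report$n_transcripts,
      " dropped_parse=", tset$report$n_dropped,
      " skipped_sequence=", n_skipped,
      " annotated=", length(annotations),
      " coding=", n_coding)
  writeLines(log_lines, files[["log"]])

  invisible(list(
    summary = summary_df, annotations = annotations, transcripts = tset,
    files = files,
    report = list(
      parsed = tset$report$n_transcripts,
      dropped_parse = tset$report$n_dropped,
      skipped_sequence = n_skipped,
      annotated = length(annotations),
      coding = n_coding
    )
  ))
}
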