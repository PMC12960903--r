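# CPAT-style coding-potential scorer: four features (ORF length, ORF
# coverage, Fickett TESTCODE statistic, in-frame hexamer usage bias) combined
# by logistic regression with a species-specific probability cutoff.

# ---------------------------------------------------------------------------
# Fickett TESTCODE statistic (lookup tables from Fickett, NAR 1982).
# Position parameter: for each base, counts at the three codon positions are
# reduced to max/(min + 1); content parameter: base fraction.  Each value is
# binned by the published thresholds and converted to a probability that is
# weighted by the published per-base weight; the TESTCODE score is the sum of
# the eight weighted probabilities.

.FICKETT_POSITION_PARA <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)
.FICKETT_CONTENT_PARA <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.17, 0, 0)

.FICKETT_POSITION_PROB <- list(
  A = c(0.51, 0.55, 0.57, 0.52, 0.48, 0.58, 0.57, 0.54, 0.50, 0.36),
  C = c(0.29, 0.44, 0.55, 0.49, 0.52, 0.60, 0.60, 0.56, 0.51, 0.38),
  G = c(0.62, 0.67, 0.74, 0.65, 0.61, 0.62, 0.66, 0.63, 0.48, 0.29),
  T = c(0.51, 0.60, 0.69, 0.64, 0.62, 0.67, 0.58, 0.48, 0.39, 0.24)
)
.FICKETT_POSITION_WEIGHT <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)

.FICKETT_CONTENT_PROB <- list(
  A = c(0.40, 0.55, 0.58, 0.58, 0.52, 0.48, 0.45, 0.45, 0.38, 0.19),
  C = c(0.50, 0.63, 0.59, 0.50, 0.41, 0.30, 0.33, 0.29, 0.29, 0.17),
  G = c(0.21, 0.40, 0.47, 0.50, 0.52, 0.60, 0.61, 0.62, 0.66, 0.72),
  T = c(0.30, 0.49, 0.56, 0.53, 0.48, 0.48, 0.34, 0.20, 0.12, 0.09)
)
.FICKETT_CONTENT_WEIGHT <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)

.fickett_lookup <- function(value, para, prob) {
  prob[which(value >= para)[1]]
}

#' Fickett TESTCODE score
#'
#' Classical coding-potential statistic combining positional base asymmetry
#' (how unevenly each base distributes over the three codon positions) and
#' base composition, through the published TESTCODE lookup tables.  `N` bases
#' are treated as uninformative and excluded from both statistics.
#'
#' @param seq Nucleotide string, length >= 2 with at least one A/C/G/T.
#' @return Numeric score (higher = more coding-like); deterministic.
#' @export
fickett_score <- function(seq) {
  seq <- toupper(seq)
  if (!is.character(seq) || length(seq) != 1 || nchar(seq) < 2) {
    stop("fickett_score() needs a single sequence of length >= 2", call. = FALSE)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  informative <- chars %in% c("A", "C", "G", "T")
  if (!any(informative)) {
    stop("sequence contains no A/C/G/T bases", call. = FALSE)
  }
  pos <- (seq_along(chars) - 1L) %% 3L
  n_inf <- sum(informative)
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    hit <- chars == b
    cnt <- vapply(0:2, function(k) sum(hit & pos == k), 0L)
    posval <- max(cnt) / (min(cnt) + 1)
    content <- sum(hit) / n_inf
    score <- score +
      .fickett_lookup(posval, .FICKETT_POSITION_PARA, .FICKETT_POSITION_PROB[[b]]) *
        .FICKETT_POSITION_WEIGHT[[b]] +
      .fickett_lookup(content, .FICKETT_CONTENT_PARA, .FICKETT_CONTENT_PROB[[b]]) *
        .FICKETT_CONTENT_WEIGHT[[b]]
  }
  score
}

# ---------------------------------------------------------------------------
# Hexamer usage bias

.all_hexamers <- function() {
  if (is.null(.orfscribe_env$hexamers)) {
    .orfscribe_env$hexamers <- names(Biostrings::oligonucleotideFrequency(
      Biostrings::DNAString("A"), width = 6L
    ))
  }
  .orfscribe_env$hexamers
}

.as_dnaset <- function(x) {
  if (inherits(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    return(Biostrings::readDNAStringSet(x))
  }
  Biostrings::DNAStringSet(toupper(x))
}

#' Build a hexamer frequency table from coding and non-coding sequences
#'
#' Coding frequencies are counted over in-frame hexamers (step 3, frame 0;
#' the coding input must therefore be in-frame CDS), non-coding frequencies
#' over hexamers at every offset (step 1).  A pseudo-count of 1 per hexamer
#' is added before normalization, so all 4096 frequencies are positive and
#' each class sums to 1.  Hexamers containing non-ACGT characters never
#' contribute.
#'
#' @param coding_seqs,noncoding_seqs Character vector of sequences,
#'   `DNAStringSet`, or path to a FASTA file.
#' @return A `hexamer_table`: list with `coding`, `noncoding` (named
#'   frequency vectors over the 4096 hexamers) and `log_ratio`
#'   (`log(coding/noncoding)`, natural log).
#' @export
build_hexamer_table <- function(coding_seqs, noncoding_seqs) {
  cod <- .as_dnaset(coding_seqs)
  non <- .as_dnaset(noncoding_seqs)
  if (length(cod) == 0 || length(non) == 0) {
    stop("both coding and noncoding training sets must be non-empty",
         call. = FALSE)
  }
  cnt_c <- colSums(Biostrings::oligonucleotideFrequency(cod, width = 6L, step = 3L))
  cnt_n <- colSums(Biostrings::oligonucleotideFrequency(non, width = 6L, step = 1L))
  f_c <- (cnt_c + 1) / sum(cnt_c + 1)
  f_n <- (cnt_n + 1) / sum(cnt_n + 1)
  structure(
    list(coding = f_c, noncoding = f_n, log_ratio = log(f_c / f_n)),
    class = "hexamer_table"
  )
}

#' Uniform hexamer table (all log-ratios zero)
#'
#' Useful for scorers that should depend on length/coverage only, e.g. the
#' length-dominant model used to validate planted fixtures.
#' @return A `hexamer_table`.
#' @export
uniform_hexamer_table <- function() {
  hx <- .all_hexamers()
  f <- stats::setNames(rep(1 / 4096, 4096), hx)
  structure(list(coding = f, noncoding = f,
                 log_ratio = stats::setNames(rep(0, 4096), hx)),
            class = "hexamer_table")
}

#' Mean in-frame hexamer log-ratio of an ORF
#'
#' Mean over the ORF's in-frame hexamers (step 3) of
#' `ln(coding_freq / noncoding_freq)`.  Hexamers containing `N` are skipped;
#' sequences shorter than 6 nt, or with all hexamers skipped, score 0.
#'
#' @param orf_seq ORF nucleotide string (frame 0 = position 1).
#' @param table A `hexamer_table`.
#' @return Numeric score.
#' @export
hexamer_score <- function(orf_seq, table) {
  stopifnot(inherits(table, "hexamer_table"))
  if (nchar(orf_seq) < 6) return(0)
  cnt <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(toupper(orf_seq)), width = 6L, step = 3L
  )
  tot <- sum(cnt)
  if (tot == 0) return(0)
  sum(cnt * table$log_ratio) / tot
}

# ---------------------------------------------------------------------------
# Coding model

#' Construct a coding-potential model
#'
#' @param hexamer_table A `hexamer_table`.
#' @param coefficients Numeric length-5 vector: intercept plus weights for
#'   `log(orf_length)`, `orf_coverage`, `fickett`, `hexamer`.
#' @param cutoff Coding-probability threshold in `[0, 1]`; `prob >= cutoff`
#'   classifies as coding.
#' @param species_label Free-text label stored with the model.
#' @return A `coding_model`.
#' @export
coding_model <- function(hexamer_table, coefficients, cutoff = 0.5,
                         species_label = "custom") {
  stopifnot(inherits(hexamer_table, "hexamer_table"),
            is.numeric(coefficients), length(coefficients) == 5,
            cutoff >= 0, cutoff <= 1)
  names(coefficients) <- c("intercept", "log_orf_length", "orf_coverage",
                           "fickett", "hexamer")
  structure(
    list(hexamer_table = hexamer_table, coefficients = coefficients,
         cutoff = cutoff, species_label = species_label),
    class = "coding_model"
  )
}

#' @export
print.coding_model <- function(x, ...) {
  cat("<coding_model> ", x$species_label, " (cutoff ", x$cutoff, ")\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Recommended species coding-probability cutoffs
#'
#' The defaults mirror the cutoffs published in the CPAT documentation
#' (human 0.364, mouse 0.44, fly 0.39, zebrafish 0.38); they are adopted
#' from that source, not derived here, and any user-supplied cutoff
#' overrides them.
#'
#' @param species One of `"human"`, `"mouse"`, `"fly"`, `"zebrafish"`.
#' @return Numeric cutoff.
#' @export
species_cutoff <- function(species) {
  cutoffs <- c(human = 0.364, mouse = 0.44, fly = 0.39, zebrafish = 0.38)
  if (!species %in% names(cutoffs)) {
    stop("no recommended cutoff for species '", species, "'; known: ",
         paste(names(cutoffs), collapse = ", "), call. = FALSE)
  }
  unname(cutoffs[[species]])
}

#' Extract the feature vector of an ORF
#'
#' ORF length and hexamer bias are computed on the ORF sequence; the Fickett
#' statistic is computed on the full transcript sequence (the ORF's
#' transcript context); coverage is ORF length / transcript length.
#'
#' @param orf_seq ORF nucleotide string (ATG..stop, length multiple of 3).
#' @param tx_seq Full transcript sequence containing the ORF.
#' @param table A `hexamer_table`.
#' @return Named list: `orf_length`, `orf_coverage`, `fickett`, `hexamer`.
#' @export
orf_features <- function(orf_seq, tx_seq, table) {
  ol <- nchar(orf_seq)
  list(
    orf_length = ol,
    orf_coverage = ol / nchar(tx_seq),
    fickett = fickett_score(tx_seq),
    hexamer = hexamer_score(orf_seq, table)
  )
}

#' Coding probability of a feature vector under a model
#'
#' Logistic link on `intercept + sum(weight * feature)` with ORF length
#' entering as its natural logarithm.
#'
#' @param fv Feature list/row with `orf_length`, `orf_coverage`, `fickett`,
#'   `hexamer` (vectorized over equal-length inputs).
#' @param model A `coding_model`.
#' @return Probability in (0, 1).
#' @export
coding_probability <- function(fv, model) {
  stopifnot(inherits(model, "coding_model"))
  b <- model$coefficients
  eta <- b[["intercept"]] +
    b[["log_orf_length"]] * log(fv$orf_length) +
    b[["orf_coverage"]] * fv$orf_coverage +
    b[["fickett"]] * fv$fickett +
    b[["hexamer"]] * fv$hexamer
  stats::plogis(eta)
}

#' Classify a coding probability against a cutoff
#'
#' The boundary case counts as coding: `prob >= cutoff`.
#'
#' @param prob Probability (vectorized).
#' @param cutoff Cutoff in `[0, 1]`.
#' @return `"coding"` or `"noncoding"`.
#' @export
classify_coding <- function(prob, cutoff) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  ifelse(prob >= cutoff, "coding", "noncoding")
}

# ---------------------------------------------------------------------------
# Training and serialization

#' Train a coding-potential model from labelled sequence sets
#'
#' Builds the hexamer table from the training sets (the longest ORF of each
#' coding sequence supplies the in-frame hexamers; non-coding sequences are
#' counted at every offset), extracts one feature vector per sequence from
#' its longest ORF, and fits the logistic coefficients by maximum likelihood
#' ([stats::glm()]).  Sequences without any complete ORF contribute no
#' feature vector; an entire class without ORFs is a training error.
#'
#' @param coding_seqs,noncoding_seqs Character vectors, `DNAStringSet`s, or
#'   FASTA paths.
#' @param seed Integer; fixed for reproducibility of the training run.
#' @param species_label Label stored with the model; when it matches a known
#'   species the recommended cutoff is used unless `cutoff` is given.
#' @param cutoff Optional cutoff override (default: species cutoff if known,
#'   else 0.5).
#' @return A `coding_model`.
#' @export
train_coding_model <- function(coding_seqs, noncoding_seqs, seed = 1L,
                               species_label = "custom", cutoff = NULL) {
  set.seed(seed)
  cod <- as.character(.as_dnaset(coding_seqs))
  non <- as.character(.as_dnaset(noncoding_seqs))

  longest_orf <- function(s) {
    orfs <- enumerate_orfs(s)
    if (nrow(orfs) == 0) return(NULL)
    i <- which.max(orfs$t_end - orfs$t_start)
    substr(s, orfs$t_start[i] + 1L, orfs$t_end[i])
  }
  orf_c <- lapply(cod, longest_orf)
  orf_n <- lapply(non, longest_orf)
  keep_c <- !vapply(orf_c, is.null, TRUE)
  keep_n <- !vapply(orf_n, is.null, TRUE)
  if (!any(keep_c) || !any(keep_n)) {
    stop("training error: no complete ORFs found in one of the classes",
         call. = FALSE)
  }
  tab <- build_hexamer_table(unlist(orf_c[keep_c]), non)

  fv <- function(txs, orfs) {
    t(vapply(seq_along(txs), function(i) {
      f <- orf_features(orfs[[i]], txs[i], tab)
      c(log_len = log(f$orf_length), cov = f$orf_coverage,
        fick = f$fickett, hex = f$hexamer)
    }, numeric(4)))
  }
  X <- rbind(fv(cod[keep_c], orf_c[keep_c]), fv(non[keep_n], orf_n[keep_n]))
  y <- c(rep(1L, sum(keep_c)), rep(0L, sum(keep_n)))
  dat <- data.frame(y = y, X)
  fit <- suppressWarnings(
    stats::glm(y ~ log_len + cov + fick + hex, data = dat,
               family = stats::binomial())
  )
  cf <- unname(stats::coef(fit))
  cf[is.na(cf)] <- 0
  if (is.null(cutoff)) {
    cutoff <- tryCatch(species_cutoff(species_label), error = function(e) 0.5)
  }
  coding_model(tab, cf, cutoff = cutoff, species_label = species_label)
}

#' Save a coding model to JSON
#'
#' Full-precision serialization: a save/load round trip reproduces
#' probabilities bit-exactly.
#'
#' @param model A `coding_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_coding_model <- function(model, path) {
  stopifnot(inherits(model, "coding_model"))
  # doubles are stored as "%.17g" strings: decimal shortest-exact notation
  # that as.numeric() parses back to the identical IEEE-754 value
  g17 <- function(x) sprintf("%.17g", x)
  obj <- list(
    format = "orfscribe_coding_model",
    version = 1L,
    species_label = model$species_label,
    cutoff = g17(model$cutoff),
    coefficients = as.list(stats::setNames(g17(model$coefficients),
                                           names(model$coefficients))),
    hexamer_coding = g17(unname(model$hexamer_table$coding)),
    hexamer_noncoding = g17(unname(model$hexamer_table$noncoding))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' Load a coding model from JSON
#'
#' @param path Path written by [save_coding_model()].
#' @return A `coding_model`.
#' @export
load_coding_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "orfscribe_coding_model")) {
    stop("not an orfscribe coding model file: ", path, call. = FALSE)
  }
  hx <- .all_hexamers()
  f_c <- stats::setNames(as.numeric(obj$hexamer_coding), hx)
  f_n <- stats::setNames(as.numeric(obj$hexamer_noncoding), hx)
  tab <- structure(list(coding = f_c, noncoding = f_n,
                        log_ratio = log(f_c / f_n)),
                   class = "hexamer_table")
  coding_model(tab, as.numeric(unlist(obj$coefficients)),
               cutoff = as.numeric(obj$cutoff),
               species_label = obj$species_label)
}

#' A scorer driven by ORF length only
#'
#' Uniform hexamer table and zero weights on coverage/Fickett/hexamer, so the
#' coding probability is a monotone function of ORF length alone.  Used to
#' validate planted fixtures, where the designed ORF is the longest by
#' construction.
#'
#' @param intercept,slope Logistic coefficients on `log(orf_length)`.
#' @param cutoff Classification cutoff.
#' @return A `coding_model`.
#' @export
length_dominant_model <- function(intercept = -8, slope = 2, cutoff = 0.5) {
  coding_model(uniform_hexamer_table(),
               c(intercept, slope, 0, 0, 0),
               cutoff = cutoff, species_label = "length_dominant")
}
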