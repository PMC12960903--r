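# GTF/GFF3 reading and faithful re-emission.
#
# Internally all coordinates are 0-based half-open; the 1-based inclusive
# convention of GTF/GFF3 exists only at the parse/serialize boundary.
# Original file lines are retained verbatim so that the annotated output
# contains every input record unchanged, with inserted CDS/UTR records
# grouped after their transcript's original lines.

.GTF_ATTR_RE <- "([A-Za-z_][A-Za-z0-9_]*)\\s+\"([^\"]*)\""

.parse_gtf_attrs <- function(s) {
  m <- regmatches(s, gregexpr(.GTF_ATTR_RE, s))[[1]]
  if (length(m) == 0) return(character(0))
  keys <- sub(.GTF_ATTR_RE, "\\1", m)
  vals <- sub(.GTF_ATTR_RE, "\\2", m)
  stats::setNames(vals, keys)
}

.parse_gff3_attrs <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  if (length(parts) == 0) return(character(0))
  kv <- strsplit(parts, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  stats::setNames(vals, keys)
}

.attr_field <- function(attr_col, key, dialect) {
  if (dialect == "gtf") {
    re <- paste0(key, "\\s+\"([^\"]*)\"")
  } else {
    re <- paste0("(?:^|;)\\s*", key, "=([^;]*)")
  }
  m <- regexpr(re, attr_col, perl = TRUE)
  out <- rep(NA_character_, length(attr_col))
  hit <- which(m > 0)
  if (length(hit)) {
    out[hit] <- sub(re, "\\1", regmatches(attr_col, m), perl = TRUE)
  }
  out
}

#' Parse a GTF or GFF3 transcript annotation
#'
#' Groups exon features into transcript models (GTF `transcript_id`
#' attribute, or GFF3 `Parent` chain).  Exons are deduplicated and sorted in
#' ascending genomic order regardless of strand.  Transcripts with invalid
#' records (end before start, unknown strand, mixed contigs) are dropped
#' with a warning and counted in the run report; transcripts that have exon
#' features but no transcript-level line are still produced.  Original file
#' lines are retained for faithful re-emission by [write_annotation()].
#'
#' @param path GTF/GFF3 file path.
#' @param dialect `"gtf"`, `"gff3"`, or `"auto"` (detect from the attribute
#'   column / file extension).
#' @return A `transcript_set`: list with `models` (named list of
#'   `transcript_model`), `lines` (verbatim input lines), `line_tx`
#'   (transcript id owning each line, `NA` otherwise), `dialect`, and
#'   `report` (parse counts).  Each `transcript_model` carries
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `exons` (n x 2 matrix,
#'   0-based half-open, ascending), `attributes`, and `source_line_order`.
#' @export
parse_annotation <- function(path, dialect = c("auto", "gtf", "gff3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_feat <- !grepl("^\\s*(#|$)", lines)
  fidx <- which(is_feat)
  parts <- strsplit(lines[fidx], "\t", fixed = TRUE)
  ok9 <- lengths(parts) >= 9L
  if (any(!ok9)) {
    warning(sum(!ok9), " malformed line(s) with fewer than 9 columns ignored",
            call. = FALSE)
    parts <- parts[ok9]
    fidx <- fidx[ok9]
  }
  col <- function(i) vapply(parts, `[`, "", i)
  attr_col <- col(9L)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext %in% c("gff", "gff3")) {
      "gff3"
    } else if (ext == "gtf") {
      "gtf"
    } else if (length(attr_col) && mean(grepl("\"", attr_col)) >= 0.5) {
      "gtf"
    } else {
      "gff3"
    }
  }

  type <- col(3L)
  chrom <- col(1L)
  start1 <- suppressWarnings(as.integer(col(4L)))
  end1 <- suppressWarnings(as.integer(col(5L)))
  strand <- col(7L)

  if (dialect == "gtf") {
    tid <- .attr_field(attr_col, "transcript_id", "gtf")
    gid <- .attr_field(attr_col, "gene_id", "gtf")
    is_tx_line <- type %in% c("transcript", "mRNA")
  } else {
    ids <- .attr_field(attr_col, "ID", "gff3")
    parent <- .attr_field(attr_col, "Parent", "gff3")
    # multi-parent exons are out of scope: keep the first parent
    multi <- grepl(",", parent, fixed = TRUE)
    if (any(multi, na.rm = TRUE)) {
      warning("multi-parent GFF3 features: only the first Parent is used",
              call. = FALSE)
      parent[which(multi)] <- sub(",.*", "", parent[which(multi)])
    }
    is_tx_line <- type %in% c("mRNA", "transcript") |
      (!is.na(ids) & ids %in% parent[type == "exon"])
    is_tx_line[type == "exon"] <- FALSE
    tid <- ifelse(is_tx_line, ids, parent)
    gid <- ifelse(is_tx_line, parent, .attr_field(attr_col, "gene_id", "gff3"))
  }

  is_exon <- type == "exon"
  exon_tids <- unique(tid[is_exon & !is.na(tid)])

  report <- list(
    n_lines = length(lines), n_feature_lines = length(fidx),
    n_transcripts = 0L, n_dropped = 0L, n_dedup_exons = 0L,
    dropped = character(0)
  )

  models <- vector("list", length(exon_tids))
  names(models) <- exon_tids
  keep <- logical(length(exon_tids))

  tx_line_pos <- which(is_tx_line & !is.na(tid))
  tx_line_of <- stats::setNames(tx_line_pos, tid[tx_line_pos])

  exon_rows <- which(is_exon & !is.na(tid))
  exon_split <- split(exon_rows, tid[exon_rows])

  for (t in exon_tids) {
    rows <- exon_split[[t]]
    st <- start1[rows]; en <- end1[rows]
    str_t <- unique(strand[rows]); chr_t <- unique(chrom[rows])
    drop_reason <- NULL
    if (any(is.na(st)) || any(is.na(en)) || any(en < st)) {
      drop_reason <- "invalid exon coordinates (end < start)"
    } else if (length(str_t) != 1 || !str_t %in% c("+", "-")) {
      drop_reason <- "unknown or inconsistent strand"
    } else if (length(chr_t) != 1) {
      drop_reason <- "exons on multiple contigs"
    }
    if (is.null(drop_reason)) {
      ex <- unique(cbind(st - 1L, en)) # 0-based half-open
      if (nrow(ex) < length(rows)) {
        report$n_dedup_exons <- report$n_dedup_exons + (length(rows) - nrow(ex))
        warning("duplicate exon lines for transcript ", t, " deduplicated",
                call. = FALSE)
      }
      ex <- ex[order(ex[, 1]), , drop = FALSE]
      if (nrow(ex) > 1 && any(ex[-1, 1] < ex[-nrow(ex), 2])) {
        drop_reason <- "overlapping exons"
      } else {
        tx_row <- tx_line_of[t]
        attrs <- if (!is.na(tx_row)) {
          if (dialect == "gtf") .parse_gtf_attrs(attr_col[tx_row])
          else .parse_gff3_attrs(attr_col[tx_row])
        } else {
          a <- if (dialect == "gtf") .parse_gtf_attrs(attr_col[rows[1]])
               else .parse_gff3_attrs(attr_col[rows[1]])
          a[!names(a) %in% c("exon_number", "exon_id")]
        }
        g <- gid[rows[1]]
        if (is.na(g) && !is.na(tx_row)) g <- gid[tx_row]
        if (is.na(g)) g <- attrs[["gene_id"]] %||% t
        dimnames(ex) <- NULL
        models[[t]] <- structure(
          list(
            transcript_id = t, gene_id = unname(g), chrom = chr_t,
            strand = str_t, exons = ex, attributes = attrs,
            source_line_order = fidx[min(c(rows, if (!is.na(tx_row)) tx_row))]
          ),
          class = "transcript_model"
        )
        keep[match(t, exon_tids)] <- TRUE
      }
    }
    if (!is.null(drop_reason)) {
      warning("transcript ", t, " dropped: ", drop_reason, call. = FALSE)
      report$n_dropped <- report$n_dropped + 1L
      report$dropped <- c(report$dropped, t)
    }
  }
  models <- models[keep]
  # preserve input encounter order
  ord <- order(vapply(models, function(m) m$source_line_order, 0))
  models <- models[ord]
  report$n_transcripts <- length(models)

  line_tx <- rep(NA_character_, length(lines))
  line_tx[fidx] <- tid
  structure(
    list(models = models, lines = lines, line_tx = line_tx,
         dialect = dialect, report = report),
    class = "transcript_set"
  )
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("<transcript_set> ", x$report$n_transcripts, " transcripts (",
      x$dialect, "), ", x$report$n_dropped, " dropped\n", sep = "")
  invisible(x)
}

#' Build CDS and UTR feature records for an annotated transcript
#'
#' Projects the primary ORF and the UTR intervals through the coordinate map
#' and assigns the GTF frame of each CDS block as
#' `(3 - (cumulative CDS nucleotides 5' of the block mod 3)) mod 3`,
#' accumulated in transcript order.  The emitted CDS includes the stop codon;
#' the 3'UTR begins immediately after it.  Non-coding transcripts yield no
#' records.
#'
#' @param model A `transcript_model`.
#' @param annotation A `transcript_annotation` (see [annotate_transcript()]).
#' @param source Value for the GTF/GFF3 source column.
#' @return data.frame of feature records in transcript 5' to 3' order with
#'   columns `chrom`, `source`, `type`, `start`, `end` (0-based half-open),
#'   `strand`, `frame` (`"0"/"1"/"2"` for CDS, `"."` otherwise),
#'   `transcript_id`, `gene_id`.
#' @export
build_feature_records <- function(model, annotation, source = "orfscribe") {
  if (!isTRUE(annotation$coding)) {
    return(.empty_records())
  }
  map <- annotation$map
  ts <- annotation$orf$t_start; te <- annotation$orf$t_end
  cds <- project_to_genome(map, ts, te)
  lens <- cds$g_end - cds$g_start
  if (sum(lens) != te - ts) {
    stop("internal consistency error: CDS blocks do not tile the ORF interval",
         call. = FALSE)
  }
  cum5 <- cumsum(c(0L, lens[-length(lens)]))
  frame <- as.character((3L - (cum5 %% 3L)) %% 3L)
  recs <- list()
  if (ts > 0) {
    u5 <- project_to_genome(map, 0L, ts)
    recs[[length(recs) + 1L]] <- .mk_records(model, "five_prime_utr", u5, ".", source)
  }
  recs[[length(recs) + 1L]] <- .mk_records(model, "CDS", cds, frame, source)
  if (te < map$transcript_length) {
    u3 <- project_to_genome(map, te, map$transcript_length)
    recs[[length(recs) + 1L]] <- .mk_records(model, "three_prime_utr", u3, ".", source)
  }
  do.call(rbind, recs)
}

.empty_records <- function() {
  data.frame(chrom = character(0), source = character(0), type = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             frame = character(0), transcript_id = character(0),
             gene_id = character(0))
}

.mk_records <- function(model, type, blocks, frame, source) {
  data.frame(
    chrom = model$chrom, source = source, type = type,
    start = blocks$g_start, end = blocks$g_end, strand = model$strand,
    frame = frame, transcript_id = model$transcript_id,
    gene_id = model$gene_id
  )
}

.serialize_record <- function(r, dialect, k) {
  if (dialect == "gtf") {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\tgene_id \"%s\"; transcript_id \"%s\";",
            r$chrom, r$source, r$type, r$start + 1L, r$end, r$strand, r$frame,
            r$gene_id, r$transcript_id)
  } else {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\tID=%s:%s:%d;Parent=%s",
            r$chrom, r$source, r$type, r$start + 1L, r$end, r$strand, r$frame,
            r$transcript_id, tolower(r$type), k, r$transcript_id)
  }
}

#' Write an annotated GTF/GFF3 file
#'
#' Emits every original input line verbatim, in the original order, and
#' groups inserted CDS/UTR records immediately after the last original line
#' of their transcript.  Coordinates are serialized 1-based inclusive.
#'
#' @param tset A `transcript_set` from [parse_annotation()].
#' @param records `NULL`, or a named list (by transcript id) of record
#'   data.frames from [build_feature_records()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(tset, records = NULL, path) {
  stopifnot(inherits(tset, "transcript_set"))
  records <- records %||% list()
  records <- records[vapply(records, NROW, 0L) > 0]
  if (length(records) > 0 &&
      !all(names(records) %in% names(tset$models))) {
    stop("inserted records reference unparsed transcripts: ",
         paste(setdiff(names(records), names(tset$models)), collapse = ", "),
         call. = FALSE)
  }
  insert_after <- rep(NA_character_, length(tset$lines))
  if (length(records) > 0) {
    last_line <- vapply(
      names(records),
      function(t) max(which(tset$line_tx == t)),
      0L
    )
    ser <- vapply(
      names(records),
      function(t) {
        df <- records[[t]]
        paste(vapply(seq_len(nrow(df)), function(i) {
          .serialize_record(df[i, ], tset$dialect, i)
        }, ""), collapse = "\n")
      },
      ""
    )
    insert_after[last_line] <- ser
  }
  out <- character(0)
  has_ins <- !is.na(insert_after)
  if (!any(has_ins)) {
    out <- tset$lines
  } else {
    chunks <- ifelse(has_ins, paste(tset$lines, insert_after, sep = "\n"),
                     tset$lines)
    out <- chunks
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}
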