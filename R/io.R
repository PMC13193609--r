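#' Load a gene annotation and derive 3' windows
#'
#' Accepts GFF3 (1-based inclusive) or BED (0-based half-open); both are
#' normalized to the internal 1-based inclusive convention before the
#' strand-aware 3' windows are computed.
#'
#' @param path GFF3 (.gff/.gff3) or BED (.bed) file.
#' @param feature_type for GFF3, keep records of this type (NULL = all).
#' @param upstream,downstream window extents, bases.
#' @return data.frame from [gene_windows()] (gene_id, contig, strand, end3,
#'   win_start, win_end) with the normalized `start`/`end` attached.
#' @export
load_gene_annotation <- function(path, feature_type = "gene",
                                 upstream = 50, downstream = 250) {
  ext <- tolower(tools::file_ext(path))
  gr <- tryCatch(
    rtracklayer::import(path),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e)))
  df <- as.data.frame(gr)
  if (ext %in% c("gff", "gff3") && !is.null(df$type) &&
      !is.null(feature_type) && any(df$type == feature_type))
    df <- df[df$type == feature_type, ]
  ids <- df$Name %||% df$ID %||% df$name
  if (is.null(ids)) ids <- sprintf("feature%04d", seq_len(nrow(df)))
  ids <- as.character(ids)
  ids[is.na(ids) | ids == ""] <- sprintf("feature%04d", which(is.na(ids) |
                                                                ids == ""))
  if (any(!df$strand %in% c("+", "-")))
    stop("unstranded feature(s) in ", path)
  ann <- data.frame(gene_id = ids, contig = as.character(df$seqnames),
                    start = df$start, end = df$end,
                    strand = as.character(df$strand),
                    stringsAsFactors = FALSE)
  w <- gene_windows(ann, upstream, downstream)
  w$start <- ann$start
  w$end <- ann$end
  w
}

#' Write a minimal GFF3 gene annotation
#'
#' @param annotation data.frame: gene_id, contig, start, end (1-based
#'   inclusive), strand.
#' @param path output file.
#' @export
write_gff3 <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\tcondensateR\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                     annotation$contig, annotation$start, annotation$end,
                     annotation$strand, annotation$gene_id,
                     annotation$gene_id), con)
  invisible(path)
}

#' Read a trajectory CSV
#'
#' Expects columns track_id, frame, x_um, y_um. Rows may be in any order;
#' duplicate (track, frame) pairs are an error.
#'
#' @param path CSV file.
#' @param frame_interval seconds (stored on the returned set).
#' @return a `trajectory_set`.
#' @export
load_trajectories <- function(path, frame_interval = 0.02) {
  tr <- utils::read.csv(path)
  need <- c("track_id", "frame", "x_um", "y_um")
  if (!all(need %in% names(tr)))
    stop("trajectory CSV must have columns: ", paste(need, collapse = ", "))
  dup <- duplicated(tr[, c("track_id", "frame")])
  if (any(dup))
    stop("duplicate (track, frame) rows for track(s): ",
         paste(unique(tr$track_id[dup]), collapse = ", "))
  if (any(!is.finite(tr$x_um)) || any(!is.finite(tr$y_um)))
    stop("non-finite positions")
  tr <- tr[order(tr$track_id, tr$frame), ]
  rownames(tr) <- NULL
  counts <- table(tr$track_id)
  structure(list(tracks = tr, frame_interval = frame_interval,
                 field_size = c(max(tr$x_um), max(tr$y_um)),
                 foci = NULL,
                 truth = NULL),
            class = "trajectory_set")
}

#' Write a trajectory CSV
#'
#' @param trajectory_set a `trajectory_set` (or tracks data.frame).
#' @param path output CSV.
#' @export
write_trajectories <- function(trajectory_set, path) {
  tr <- if (inherits(trajectory_set, "trajectory_set"))
    trajectory_set$tracks else trajectory_set
  utils::write.csv(tr[, c("track_id", "frame", "x_um", "y_um")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write a count matrix TSV with spike-in rows
#'
#' @param counts matrix with row and column names (spike-ins prefixed, by
#'   convention, with `ERCC-`).
#' @param path output TSV.
#' @export
write_count_matrix <- function(counts, path) {
  utils::write.table(data.frame(feature = rownames(counts), counts,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix TSV written by [write_count_matrix()]
#'
#' @param path TSV file.
#' @return numeric matrix with feature row names.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write read records as TSV (and optionally SAM)
#'
#' The TSV carries read_id, sample, condition, contig, start, end, strand and
#' sequence. `sam = TRUE` additionally writes a minimal unsorted SAM file of
#' the same records.
#'
#' @param reads read-record data.frame (see [simulate_polya_reads()]).
#' @param path output TSV path.
#' @param sam also write `<path>.sam`.
#' @param contig_lengths named vector for the SAM header (required if
#'   `sam = TRUE`).
#' @export
write_read_records <- function(reads, path, sam = FALSE,
                               contig_lengths = NULL) {
  keep <- intersect(c("read_id", "sample", "condition", "replicate",
                      "contig", "start", "end", "strand", "sequence"),
                    names(reads))
  utils::write.table(reads[, keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (sam) {
    stopifnot(!is.null(contig_lengths))
    sam_path <- paste0(path, ".sam")
    con <- file(sam_path, "w")
    on.exit(close(con))
    writeLines("@HD\tVN:1.6\tSO:unsorted", con)
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                       as.integer(contig_lengths)), con)
    flag <- ifelse(reads$strand == "-", 16L, 0L)
    # soft-clip the untemplated leading run; the rest matches the reference
    tail_len <- count_terminal_As(reads$sequence)
    mlen <- reads$end - reads$start + 1L
    cigar <- ifelse(tail_len > 0,
                    sprintf("%dS%dM", tail_len, mlen),
                    sprintf("%dM", mlen))
    writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                       reads$read_id, flag, reads$contig, reads$start,
                       cigar, reads$sequence), con)
  }
  invisible(path)
}

#' Read a read-record TSV
#'
#' @param path TSV written by [write_read_records()].
#' @return data.frame of read records.
#' @export
read_read_records <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write an intensity image as 16-bit TIFF
#'
#' @param image numeric matrix; rescaled into the 16-bit range via
#'   `max_value`.
#' @param path output TIFF.
#' @param max_value intensity mapped to 65535 (default: image max).
#' @export
write_image_tiff <- function(image, path, max_value = NULL) {
  if (is.null(max_value)) max_value <- max(image, 1e-12)
  img <- pmin(pmax(image / max_value, 0), 1)
  tiff::writeTIFF(img, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a TIFF image as a numeric matrix (or list of frames)
#'
#' @param path TIFF file.
#' @return matrix, or list of matrices for multi-page files.
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path, all = TRUE)
  if (length(img) == 1) img[[1]] else img
}

## per-stage parameter schemas for run_stage()
stage_params <- list(
  simulate_tracking = c("n_tracks", "state_fractions", "diffusion_coeffs",
                        "frame_interval", "localization_sigma",
                        "focus_centers", "focus_radius", "field_size",
                        "median_track_length"),
  smtrack = c("trajectories", "pixel_size", "image_shape", "msd_factor"),
  decay = c("counts", "samples"),
  polya = c("reads", "annotation_file", "mode"),
  enrich = c("values_file", "terms_file", "n_bins")
)

#' Run one analysis stage from a configuration list
#'
#' A thin reproducibility wrapper over the package functions: validates the
#' stage's parameter keys (unknown keys are rejected before execution), seeds
#' all randomness from the single run seed, executes the stage, writes its
#' output tables plus a resolved-configuration JSON into `out_dir`, and
#' returns the output paths. Identical config + seed give identical outputs.
#'
#' @param stage one of "simulate_tracking", "smtrack", "decay", "polya",
#'   "enrich".
#' @param config named list of stage parameters (file paths and settings).
#' @param out_dir output directory (created if missing).
#' @param seed integer run seed.
#' @return invisible named list of written file paths.
#' @export
run_stage <- function(stage, config = list(), out_dir, seed = 1L) {
  stage <- match.arg(stage, names(stage_params))
  unknown <- setdiff(names(config), stage_params[[stage]])
  if (length(unknown))
    stop("unknown parameter key(s) for stage ", stage, ": ",
         paste(unknown, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  emit <- function(obj, name) {
    p <- file.path(out_dir, name)
    utils::write.table(obj, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- p
    p
  }
  if (stage == "simulate_tracking") {
    cfg <- do.call(trajectory_sim_config, c(config, list(seed = seed)))
    ts <- simulate_trajectories(cfg)
    write_trajectories(ts, file.path(out_dir, "trajectories.csv"))
    paths[["trajectories.csv"]] <- file.path(out_dir, "trajectories.csv")
    emit(ts$truth, "trajectory_truth.tsv")
  } else if (stage == "smtrack") {
    ts <- load_trajectories(config$trajectories)
    shape <- config$image_shape %||% c(128, 128)
    px <- config$pixel_size %||% 0.049
    foci <- detect_stable_foci(ts, shape, px)
    cls <- classify_trajectories(ts, foci)
    emit(cls, "track_classes.tsv")
    emit(foci$regions, "focus_regions.tsv")
    pool <- pooled_squared_displacements(ts)
    fit <- fit_three_state(pool, ts$frame_interval,
                           msd_factor = config$msd_factor %||% (8 / 3),
                           seed = seed)
    tr <- ts$tracks
    cls_by_track <- cls$label[match(tr$track_id, cls$track_id)]
    sub_ids <- cls$track_id[cls$label %in% c("In", "InOut")]
    sub_pool <- pooled_squared_displacements(
      tr[tr$track_id %in% sub_ids, , drop = FALSE])
    counts <- table(factor(cls_by_track, levels = c("In", "InOut", "Out")))
    frac <- NULL
    if (length(sub_pool) >= 100) {
      sub_fit <- fit_three_state(sub_pool, ts$frame_interval,
                                 msd_factor = config$msd_factor %||% (8 / 3),
                                 seed = seed)
      n_steps <- function(ids) length(pooled_squared_displacements(
        tr[tr$track_id %in% ids, , drop = FALSE]))
      frac <- compute_state_fractions(
        fit, sub_fit,
        n_in = n_steps(cls$track_id[cls$label == "In"]),
        n_inout = n_steps(cls$track_id[cls$label == "InOut"]),
        n_total = length(pool))
    }
    report <- list(three_state = unclass(fit),
                   fractions = if (is.null(frac)) NULL else unclass(frac),
                   n_tracks = length(unique(tr$track_id)),
                   n_displacements = length(pool))
    p <- file.path(out_dir, "smtrack_report.json")
    jsonlite::write_json(report, p, auto_unbox = TRUE, digits = 10,
                         null = "null")
    paths[["smtrack_report.json"]] <- p
  } else if (stage == "decay") {
    counts <- read_count_matrix(config$counts)
    samples <- utils::read.delim(config$samples)
    norm <- normalize_counts(counts)
    fits <- fit_decay_matrix(norm, samples)
    emit(fits, "decay_fits.tsv")
  } else if (stage == "polya") {
    reads <- read_read_records(config$reads)
    w <- load_gene_annotation(config$annotation_file)
    ann <- data.frame(gene_id = w$gene_id, contig = w$contig,
                      start = w$start, end = w$end, strand = w$strand)
    obs <- tail_observations(reads, ann, mode = config$mode %||% "run")
    fits <- fit_all_zinb(obs)
    tab <- do.call(rbind, lapply(names(fits), function(g) {
      f <- fits[[g]]
      data.frame(gene_id = g, condition = names(f$mu), mu = as.numeric(f$mu),
                 mean_tail = as.numeric(f$mean_tail),
                 zero_inflation = f$zero_inflation,
                 overdispersion = f$overdispersion, converged = f$converged)
    }))
    emit(tab, "polya_fits.tsv")
  } else if (stage == "enrich") {
    vals <- utils::read.delim(config$values_file)
    terms <- utils::read.delim(config$terms_file)
    bins <- quintile_bins(vals$value, config$n_bins %||% 5)
    universe <- vals$gene_id
    res <- lapply(unique(terms$term_id), function(tm) {
      members <- terms$gene_id[terms$term_id == tm]
      per_bin <- lapply(sort(unique(bins)), function(bn) {
        orr <- term_odds_ratio(members, universe[bins == bn], universe)
        data.frame(term_id = tm, bin = bn, odds_ratio = orr$odds_ratio,
                   log2_odds_ratio = orr$log2_odds_ratio,
                   p_value = orr$p_value)
      })
      do.call(rbind, per_bin)
    })
    res <- do.call(rbind, res)
    res$q_value <- stats::p.adjust(res$p_value, "BH")
    emit(res, "enrichment.tsv")
  }
  cfg_path <- file.path(out_dir, "resolved_config.json")
  jsonlite::write_json(list(stage = stage, config = config, seed = seed,
                            package_version =
                              as.character(utils::packageVersion("condensateR"))),
                       cfg_path, auto_unbox = TRUE, null = "null")
  paths[["resolved_config.json"]] <- cfg_path
  invisible(paths)
}
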