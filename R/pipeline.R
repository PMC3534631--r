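#' Analysis configuration for the end-to-end workflows
#'
#' Collects every tunable of the segment-then-call pipeline. `mode`
#' "individual" analyzes each sample on its own (stacking its LRR with its
#' mirrored BAF when `signals = "both"`, with full sharing `p = 1` between
#' the two signals of one subject); mode "joint" fits all samples' LRR
#' together with the group penalty weighted by the expected sharing
#' proportion `p` across samples.
#'
#' @param mode `"individual"` or `"joint"`.
#' @param signals `"lrr"` or `"both"` (LRR + mBAF; individual mode only).
#' @param p expected sharing proportion across samples (joint mode).
#' @param c1,c2,c3 penalty multipliers, see [default_penalties()].
#' @param sigma_method noise estimator, see [estimate_sigma()].
#' @param het_band mBAF heterozygote band, see [compute_mbaf()].
#' @param epsilon,tol,max_iter solver settings, see [penalty_config()].
#' @param threshold list: `method` (`"ruler"`/`"mbic"`) and ruler constants
#'   `a`, `b`, `c`.
#' @param calling list: `r1`, `r2_dup`, `r2_del`, see [calling_config()].
#' @param seed optional integer seed recorded for provenance.
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("individual", "joint"),
                       signals = c("both", "lrr"),
                       p = 0.3, c1 = 0.1, c2 = 1, c3 = 1,
                       sigma_method = "mad", het_band = c(0.03, 0.97),
                       epsilon = 1e-8, tol = 1e-6, max_iter = 500L,
                       threshold = list(method = "ruler", a = 1, b = 5, c = 0.2),
                       calling = list(r1 = 10, r2_dup = 1, r2_del = 1.5),
                       seed = NULL) {
  mode <- match.arg(mode)
  signals <- match.arg(signals)
  if (mode == "joint" && signals == "both") {
    stop("joint mode segments LRR only; set signals = 'lrr'", call. = FALSE)
  }
  structure(list(mode = mode, signals = signals, p = p, c1 = c1, c2 = c2,
                 c3 = c3, sigma_method = sigma_method, het_band = het_band,
                 epsilon = epsilon, tol = tol, max_iter = as.integer(max_iter),
                 threshold = threshold, calling = calling, seed = seed),
            class = "run_config")
}

row_sigma <- function(sm, method) {
  s <- vapply(seq_len(nrow(sm$values)),
              function(i) estimate_sigma(sm$values[i, ], method = method),
              numeric(1))
  setNames(s, sm$labels)
}

# Per-sequence ruler cutoffs c * gamma_i from the candidate jump sizes.
ruler_cutoffs <- function(cand, sigma, th) {
  vapply(names(sigma), function(lab) {
    D <- suppressWarnings(max(abs(cand$size[cand$sequence == lab]), 0))
    th$c * max(th$a * sigma[[lab]], min(D, th$b * sigma[[lab]]))
  }, numeric(1))
}

threshold_jumps <- function(cand, sm, sigma, th) {
  if (identical(th$method, "mbic")) {
    purrr::map_dfr(sm$labels, function(lab) {
      i <- match(lab, sm$labels)
      own <- cand[cand$sequence == lab, ]
      own[own$j %in% mbic_threshold(sm$values[i, ], own), ]
    })
  } else {
    ruler_threshold(cand, sigma, a = th$a, b = th$b, c = th$c)
  }
}

# Individual analysis of one sample on one chromosome; returns LRR segments.
segment_one_sample <- function(lrr_track, baf_track, cfg) {
  use_mbaf <- cfg$signals == "both" && !is.null(baf_track)
  if (use_mbaf) {
    mb <- compute_mbaf(baf_track$values, het_band = cfg$het_band)
    tracks <- list(
      lrr = lrr_track,
      mbaf = list(chrom = baf_track$chrom, positions = baf_track$positions,
                  values = mb$mbaf)
    )
    n_mb <- sum(is.finite(mb$mbaf))
    if (n_mb < 3) tracks$mbaf <- NULL   # too few heterozygotes to segment
    sm <- stack_sequences(tracks)
  } else {
    sm <- stack_sequences(list(lrr = lrr_track))
  }
  M <- nrow(sm$values)
  sigma <- row_sigma(sm, cfg$sigma_method)
  # two signals of one subject share all change points: p = 1
  pc <- default_penalties(sigma, N = ncol(sm$values), M = M,
                          p = if (M > 1) 1 else 0,
                          c1 = cfg$c1, c2 = cfg$c2, c3 = cfg$c3,
                          epsilon = cfg$epsilon, tol = cfg$tol,
                          max_iter = cfg$max_iter)
  fit <- fit_gfl(sm, pc)
  cand <- collapse_jumps(extract_jumps(fit, sigma = sigma))
  kept <- threshold_jumps(cand, sm, sigma, cfg$threshold)
  kept <- union_changepoints(list(kept))        # union across LRR and mBAF
  if (nrow(kept) > 0L && !identical(cfg$threshold$method, "mbic")) {
    # a union boundary must survive on the recomputed means of some signal
    kept <- prune_jumps(kept, sm, ruler_cutoffs(cand, sigma, cfg$threshold),
                        shared = TRUE)
  }
  if (nrow(kept) > 0L) {
    kept$sequence <- "lrr"                      # apply the union to the LRR row
    kept <- kept[!duplicated(kept$j), , drop = FALSE]
    kept <- refine_jumps(kept, sm, window = 10L)
  }
  segs <- jumps_to_segments(kept, sm, beta = fit$beta)
  segs <- segs[segs$sequence == "lrr", , drop = FALSE]
  attr(segs, "fit") <- fit
  segs
}

#' Segment samples chromosome by chromosome
#'
#' End-to-end segmentation of a long signal tibble: per chromosome, builds
#' the signal matrices, estimates noise, derives default penalties, runs the
#' MM solver and applies the second-stage jump threshold. In individual mode
#' each sample is fit on its own (optionally stacked with its mBAF, sharing
#' all change points); in joint mode all samples' LRR are fit together with
#' the group penalty at sharing proportion `p`. A CNV never spans
#' chromosomes, so chromosomes are processed independently and concatenated
#' in input order.
#'
#' @param signals long tibble with columns `chrom`, `position`, `sample`,
#'   `lrr` and (for `signals = "both"`) `baf`, e.g. from
#'   [read_signal_table()] .
#' @param cfg a [run_config()].
#' @return Segment tibble with a `sample` column (renamed from `sequence`),
#'   one partition of each chromosome per sample.
#' @export
run_segment <- function(signals, cfg = run_config()) {
  chroms <- unique(signals$chrom)
  out <- purrr::map_dfr(chroms, function(ch) {
    sub <- signals[signals$chrom == ch, , drop = FALSE]
    samples <- unique(sub$sample)
    if (cfg$mode == "individual") {
      purrr::map_dfr(samples, function(s) {
        df <- sub[sub$sample == s, , drop = FALSE]
        df <- df[order(df$position), , drop = FALSE]
        lrr_track <- list(chrom = ch, positions = df$position, values = df$lrr)
        baf_track <- if (cfg$signals == "both" && "baf" %in% names(df)) {
          list(chrom = ch, positions = df$position, values = df$baf)
        }
        segs <- segment_one_sample(lrr_track, baf_track, cfg)
        segs$sequence <- s
        segs
      })
    } else {
      tracks <- lapply(split(sub, sub$sample), function(df) {
        df <- df[order(df$position), , drop = FALSE]
        list(chrom = ch, positions = df$position, values = df$lrr)
      })
      sm <- stack_sequences(tracks)
      sigma <- row_sigma(sm, cfg$sigma_method)
      pc <- default_penalties(sigma, N = ncol(sm$values), M = nrow(sm$values),
                              p = cfg$p, c1 = cfg$c1, c2 = cfg$c2, c3 = cfg$c3,
                              epsilon = cfg$epsilon, tol = cfg$tol,
                              max_iter = cfg$max_iter)
      fit <- fit_gfl(sm, pc)
      cand <- collapse_jumps(extract_jumps(fit, sigma = sigma))
      kept <- threshold_jumps(cand, sm, sigma, cfg$threshold)
      if (nrow(kept) > 0L && !identical(cfg$threshold$method, "mbic")) {
        kept <- prune_jumps(kept, sm, ruler_cutoffs(cand, sigma, cfg$threshold),
                            shared = FALSE)
      }
      if (nrow(kept) > 0L) kept <- refine_jumps(kept, sm, window = 10L)
      jumps_to_segments(kept, sm, beta = fit$beta)
    }
  })
  names(out)[names(out) == "sequence"] <- "sample"
  out
}

#' Call copy-number states for segmented samples
#'
#' Applies the five-state likelihood-ratio caller to every segment, per
#' sample and chromosome, using the untransformed BAF together with LRR.
#' Emits one row per input segment, accepted or rejected with reason.
#'
#' @param segments output of [run_segment()].
#' @param signals the long signal tibble the segments were computed from.
#' @param cfg a [run_config()].
#' @param model a [state_model()].
#' @return Calls tibble: segments plus `state`, `lr`, `accepted`, `reason`.
#' @export
run_call <- function(segments, signals, cfg = run_config(), model = state_model()) {
  ccfg <- calling_config(r1 = cfg$calling$r1, r2_dup = cfg$calling$r2_dup,
                         r2_del = cfg$calling$r2_del)
  purrr::map_dfr(unique(segments$chrom), function(ch) {
    segs <- segments[segments$chrom == ch, , drop = FALSE]
    sub <- signals[signals$chrom == ch, , drop = FALSE]
    purrr::map_dfr(unique(segs$sample), function(s) {
      df <- sub[sub$sample == s, , drop = FALSE]
      df <- df[order(df$position), , drop = FALSE]
      own <- segs[segs$sample == s, , drop = FALSE]
      sigma <- estimate_sigma(df$lrr, method = cfg$sigma_method)
      purrr::map_dfr(seq_len(nrow(own)), function(r) {
        seg <- own[r, ]
        idx <- which(df$position >= seg$start_bp & df$position <= seg$end_bp)
        res <- call_segment(
          baf = if ("baf" %in% names(df)) df$baf[idx] else numeric(0),
          lrr = df$lrr[idx], model = model, cfg = ccfg, sigma = sigma
        )
        dplyr::bind_cols(seg, res)
      })
    })
  })
}

#' Simulate a scenario and write reader-compatible files
#'
#' Drives the synthetic generators and writes the split-signal table plus the
#' truth file, so the whole pipeline can run from files. Fixed seeds give
#' identical files.
#'
#' @param scenario list with `kind` (`"cohort"`, `"tumor"` or `"pedigree"`)
#'   and the matching generator arguments (`M`, `N`, `specs`, `alpha`,
#'   `p_share`, `noise`, `seed`, ...).
#' @param prefix output path prefix; writes `<prefix>_signals.tsv` and
#'   `<prefix>_truth.tsv`.
#' @return The generated data (invisibly) with `files` attached.
#' @export
run_simulate <- function(scenario, prefix) {
  kind <- scenario$kind
  if (is.null(kind) || !kind %in% c("cohort", "tumor", "pedigree")) {
    stop("scenario$kind must be one of 'cohort', 'tumor', 'pedigree'", call. = FALSE)
  }
  args <- scenario[setdiff(names(scenario), "kind")]
  sim <- switch(kind,
    cohort = do.call(generate_cohort, args),
    tumor = do.call(generate_tumor_dilution, args),
    pedigree = do.call(generate_pedigree_cohort, args)
  )
  long <- dplyr::left_join(
    dplyr::rename(tidy.signal_matrix(sim$lrr), lrr = "value", sample = "sequence"),
    dplyr::rename(tidy.signal_matrix(sim$baf), baf = "value", sample = "sequence")[,
      c("sample", "position", "baf")],
    by = c("sample", "position")
  )
  long$probe <- long$probe
  files <- c(signals = paste0(prefix, "_signals.tsv"),
             truth = paste0(prefix, "_truth.tsv"))
  write_signal_table(long[, c("probe", "chrom", "position", "sample", "lrr", "baf")],
                     files[["signals"]])
  write_truth(sim$truth, files[["truth"]])
  sim$files <- files
  invisible(sim)
}
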