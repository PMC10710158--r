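#' Default simulated genome
#'
#' Two autosomes (60 and 40 Mb), one sex chromosome (20 Mb, placed but not
#' autosomal) and one unplaced scaffold (1 Mb), so that the placement and
#' autosome filters of the pipeline are exercised.
#' @return a [genome_def].
#' @export
sim_genome <- function() {
  genome_def(c("chr1", "chr2", "chrX", "chrUn_scaf1"),
             c(60e6, 40e6, 20e6, 1e6))
}

#' Configuration of a synthetic CNV cohort
#'
#' Describes a two-or-more-population cohort with planted CNV loci of known
#' per-population copy-number state distributions (integer states 0..6,
#' diploid baseline 2). A fraction `prop_differentiated` of loci is planted
#' with strongly divergent distributions (carrier frequency
#' `diff_carrier_freq` of a homozygous deletion in the first population
#' versus the same frequency of the reference state in the second),
#' yielding an analytic expected Vst of about 0.81 at the defaults; the
#' remaining loci share one distribution across populations (expected Vst
#' 0). Emitted calls carry Gaussian boundary jitter, Gaussian copy-number
#' noise, false-negative call suppression, and per-sample decoy calls
#' drawn uniformly on the genome (length log-uniform 1-50 kb, states 1 or
#' 3) that test the recurrence filter.
#'
#' @param n_per_pop samples per population (default 50).
#' @param populations population ids (default `"popA"`, `"popB"`).
#' @param n_loci number of planted disjoint loci (default 100).
#' @param prop_differentiated fraction of loci planted as
#'   population-differentiated (default 0.01).
#' @param diff_carrier_freq carrier frequency of the divergent state at
#'   differentiated loci (default 0.95).
#' @param locus_length_range bp range for log-uniform locus lengths
#'   (default 5-50 kb).
#' @param background_freq_range carrier-frequency range for the shared
#'   non-reference state at background loci (default 0.1-0.5).
#' @param boundary_jitter_sd sd in bp of Gaussian jitter applied
#'   independently to both breakpoints (default 200).
#' @param call_fn_rate probability that a true non-reference state emits no
#'   call (default 0.05).
#' @param decoy_call_rate per-locus-equivalent probability of a decoy call
#'   per sample; decoys per sample ~ Binomial(`n_loci`, rate)
#'   (default 0.05).
#' @param cn_noise_sd sd of additive Gaussian noise on emitted copy
#'   numbers (default 0.2).
#' @param genome a [genome_def] (default [sim_genome()]).
#' @param seed integer seed; the single source of all randomness.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_per_pop = 50, populations = c("popA", "popB"),
                       n_loci = 100, prop_differentiated = 0.01,
                       diff_carrier_freq = 0.95,
                       locus_length_range = c(5000, 50000),
                       background_freq_range = c(0.1, 0.5),
                       boundary_jitter_sd = 200, call_fn_rate = 0.05,
                       decoy_call_rate = 0.05, cn_noise_sd = 0.2,
                       genome = sim_genome(), seed = 1L) {
  rates <- c(prop_differentiated, call_fn_rate, decoy_call_rate,
             diff_carrier_freq)
  if (any(rates < 0 | rates > 1)) .stopf("rates must lie in [0, 1]")
  if (boundary_jitter_sd < 0 || cn_noise_sd < 0)
    .stopf("noise standard deviations must be >= 0")
  if (n_loci < 1L) .stopf("n_loci must be >= 1")
  structure(list(
    n_per_pop = n_per_pop, populations = populations, n_loci = n_loci,
    prop_differentiated = prop_differentiated,
    diff_carrier_freq = diff_carrier_freq,
    locus_length_range = locus_length_range,
    background_freq_range = background_freq_range,
    boundary_jitter_sd = boundary_jitter_sd, call_fn_rate = call_fn_rate,
    decoy_call_rate = decoy_call_rate, cn_noise_sd = cn_noise_sd,
    genome = genome, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Analytic expected Vst of a planted locus
#'
#' Applies the Vst definition to the generating distributions themselves:
#' within-population variances are the variances of the two copy-number
#' state distributions, the total variance is the variance of their
#' sample-size-weighted mixture, and `Vst = (Vt - Vs) / Vt` (0 when
#' `Vt = 0`).
#'
#' @param p_a,p_b probability vectors over integer copy-number states
#'   `0..(length(p)-1)` for the two populations.
#' @param n_a,n_b population sample sizes (weights; default equal).
#' @return expected Vst in `[0, 1]`.
#' @examples
#' expected_vst(c(0, 0, 0.5, 0, 0.5), c(0, 0, 1))  # 1/3
#' @export
expected_vst <- function(p_a, p_b, n_a = 1, n_b = 1) {
  k <- max(length(p_a), length(p_b))
  p_a <- c(p_a, rep(0, k - length(p_a)))
  p_b <- c(p_b, rep(0, k - length(p_b)))
  if (abs(sum(p_a) - 1) > 1e-8 || abs(sum(p_b) - 1) > 1e-8)
    .stopf("state probabilities must sum to 1")
  states <- seq_len(k) - 1
  mom <- function(p) {
    m <- sum(states * p)
    c(m = m, v = sum(states^2 * p) - m^2)
  }
  ma <- mom(p_a); mb <- mom(p_b)
  w_a <- n_a / (n_a + n_b); w_b <- 1 - w_a
  v_s <- w_a * ma[["v"]] + w_b * mb[["v"]]
  mix_m <- w_a * ma[["m"]] + w_b * mb[["m"]]
  mix_e2 <- w_a * (ma[["v"]] + ma[["m"]]^2) + w_b * (mb[["v"]] + mb[["m"]]^2)
  v_t <- mix_e2 - mix_m^2
  if (v_t <= 0) return(0)
  min(1, max(0, (v_t - v_s) / v_t))
}

# place n disjoint loci on the autosomes by rejection sampling
.place_loci <- function(n, len_range, genome) {
  autos <- genome$autosome_set
  alen <- genome$chrom_lengths[autos]
  loci <- data.frame(chrom = character(), start = numeric(),
                     end = numeric(), stringsAsFactors = FALSE)
  tries <- 0L
  while (nrow(loci) < n) {
    if ((tries <- tries + 1L) > 100L * n)
      .stopf("could not place %d disjoint loci; genome too small", n)
    len <- round(exp(stats::runif(1, log(len_range[[1L]]),
                                  log(len_range[[2L]]))))
    chrom <- sample(autos, 1L, prob = alen)
    start <- floor(stats::runif(1, 1, alen[[chrom]] - len))
    clash <- loci$chrom == chrom &
      .ov_len(loci$start, loci$end, start, start + len) > 0
    if (!any(clash))
      loci <- rbind(loci, data.frame(chrom = chrom, start = start,
                                     end = start + len,
                                     stringsAsFactors = FALSE))
  }
  loci <- loci[order(match(loci$chrom, genome$chrom_names), loci$start), ,
               drop = FALSE]
  loci$locus_id <- sprintf("locus_%03d", seq_len(nrow(loci)))
  rownames(loci) <- NULL
  loci
}

#' Simulate a multi-population CNV cohort with known truth
#'
#' Draws per-sample copy-number states at planted loci from per-population
#' distributions, emits CNV calls for non-reference states with boundary
#' jitter, copy-number noise, false negatives and decoy calls, and returns
#' the full truth needed to validate the downstream pipeline. All
#' randomness flows from `config$seed`; the caller's RNG state is left
#' untouched. User-supplied loci must be disjoint.
#'
#' @param config a [sim_config].
#' @param loci optional data.frame (`chrom`, `start`, `end`) of planted
#'   loci overriding random placement; must be pairwise disjoint.
#' @param cn_probs optional array `[locus, population, state 0..6]` of
#'   state distributions overriding the generated ones.
#' @return list of class `sim_cohort`: `calls` (a `cnv_calls` table for
#'   the whole cohort), `samples` (sample sheet), `truth` (list: `loci`
#'   data.frame with `locus_id`, coordinates, `differentiated` flag and
#'   `expected_vst`; `cn_probs` array; `states` integer matrix
#'   locus x sample), `genome`, `config`.
#' @export
simulate_cohort <- function(config, loci = NULL, cn_probs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  # run under a private RNG stream
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  genome <- config$genome
  pops <- config$populations
  samples <- data.frame(
    sample_id = unlist(lapply(pops, function(p)
      sprintf("%s_s%02d", p, seq_len(config$n_per_pop)))),
    population_id = rep(pops, each = config$n_per_pop),
    stringsAsFactors = FALSE
  )

  if (is.null(loci)) {
    loci <- .place_loci(config$n_loci, config$locus_length_range, genome)
  } else {
    loci <- as.data.frame(loci)
    if (is.null(loci$locus_id))
      loci$locus_id <- sprintf("locus_%03d", seq_len(nrow(loci)))
    for (chr in unique(loci$chrom)) {
      l <- loci[loci$chrom == chr, , drop = FALSE]
      l <- l[order(l$start), , drop = FALSE]
      if (nrow(l) > 1L && any(l$start[-1L] < l$end[-nrow(l)]))
        .stopf("planted loci must be pairwise disjoint")
    }
  }
  n_loci <- nrow(loci)
  n_states <- 7L  # integer CN 0..6

  if (is.null(cn_probs)) {
    cn_probs <- array(0, dim = c(n_loci, length(pops), n_states),
                      dimnames = list(loci$locus_id, pops,
                                      as.character(0:6)))
    n_diff <- round(config$prop_differentiated * n_loci)
    diff_idx <- if (n_diff > 0) seq_len(n_diff) else integer(0)
    f <- config$diff_carrier_freq
    for (i in seq_len(n_loci)) {
      if (i %in% diff_idx) {
        # fixed-ish difference: pop 1 mostly CN0, the others mostly CN2
        cn_probs[i, 1L, ] <- c(f, 0, 1 - f, rep(0, n_states - 3L))
        for (j in seq_along(pops)[-1L])
          cn_probs[i, j, ] <- c(1 - f, 0, f, rep(0, n_states - 3L))
      } else {
        alt <- sample(c(0L, 1L, 3L, 4L), 1L)
        q <- stats::runif(1, config$background_freq_range[[1L]],
                          config$background_freq_range[[2L]])
        p <- rep(0, n_states); p[[alt + 1L]] <- q; p[[3L]] <- p[[3L]] + 1 - q
        for (j in seq_along(pops)) cn_probs[i, j, ] <- p
      }
    }
  } else {
    stopifnot(all(dim(cn_probs) == c(n_loci, length(pops), n_states)))
  }

  # analytic truth (first two populations define expected Vst)
  loci$differentiated <- vapply(seq_len(n_loci), function(i)
    expected_vst(cn_probs[i, 1L, ], cn_probs[i, 2L, ],
                 config$n_per_pop, config$n_per_pop) >= 0.8, logical(1))
  loci$expected_vst <- vapply(seq_len(n_loci), function(i)
    expected_vst(cn_probs[i, 1L, ], cn_probs[i, 2L, ],
                 config$n_per_pop, config$n_per_pop), numeric(1))

  # draw states and emit calls
  states <- matrix(2L, nrow = n_loci, ncol = nrow(samples),
                   dimnames = list(loci$locus_id, samples$sample_id))
  call_rows <- list()
  jitter1 <- function(x) {
    if (config$boundary_jitter_sd == 0) return(x)
    round(x + stats::rnorm(1, 0, config$boundary_jitter_sd))
  }
  for (s in seq_len(nrow(samples))) {
    pop_j <- match(samples$population_id[[s]], pops)
    for (i in seq_len(n_loci)) {
      st <- sample(0:6, 1L, prob = cn_probs[i, pop_j, ])
      states[i, s] <- st
      if (st == 2L) next
      if (stats::runif(1) < config$call_fn_rate) next
      chrom_len <- genome$chrom_lengths[[loci$chrom[[i]]]]
      repeat {  # resample jitter producing empty/negative intervals
        a <- max(1, min(jitter1(loci$start[[i]]), chrom_len))
        b <- max(1, min(jitter1(loci$end[[i]]), chrom_len + 1))
        if (b > a) break
      }
      cn <- st + stats::rnorm(1, 0, config$cn_noise_sd)
      # keep the emitted copy number on its own side of the diploid baseline
      cn <- if (st < 2L) min(max(cn, 0), 1.99) else max(cn, 2.01)
      call_rows[[length(call_rows) + 1L]] <- data.frame(
        sample_id = samples$sample_id[[s]],
        population_id = samples$population_id[[s]],
        chrom = loci$chrom[[i]], start = a, end = b,
        cnv_type = if (st < 2L) "DEL" else "DUP", copy_number = cn,
        source_line = sprintf("sim:%s", loci$locus_id[[i]]),
        stringsAsFactors = FALSE
      )
    }
    # decoy calls: uniform on the whole genome, rarely recurrent
    n_decoy <- stats::rbinom(1, n_loci, config$decoy_call_rate)
    for (d in seq_len(n_decoy)) {
      chrom <- sample(genome$chrom_names, 1L,
                      prob = genome$chrom_lengths)
      len <- round(exp(stats::runif(1, log(1000), log(50000))))
      start <- floor(stats::runif(1, 1,
                                  max(2, genome$chrom_lengths[[chrom]] - len)))
      st <- sample(c(1L, 3L), 1L)
      cn <- st + stats::rnorm(1, 0, config$cn_noise_sd)
      cn <- if (st < 2L) min(max(cn, 0), 1.99) else max(cn, 2.01)
      call_rows[[length(call_rows) + 1L]] <- data.frame(
        sample_id = samples$sample_id[[s]],
        population_id = samples$population_id[[s]],
        chrom = chrom, start = start, end = start + len,
        cnv_type = if (st < 2L) "DEL" else "DUP", copy_number = cn,
        source_line = "sim:decoy", stringsAsFactors = FALSE
      )
    }
  }
  calls <- do.call(rbind, c(list(.empty_calls()), call_rows))
  calls <- .new_call_set(calls, .empty_call_errors())

  structure(list(
    calls = calls, samples = samples,
    truth = list(loci = loci, cn_probs = cn_probs, states = states),
    genome = genome, config = config
  ), class = "sim_cohort")
}

#' Write a simulated cohort to disk in the formats the readers consume
#'
#' Emits one CNVnator-dialect call file per sample (`calls/<sample>.txt`),
#' a sample sheet TSV (`samples.tsv` with `sample_id`, `population_id`,
#' `path`, `format`), a chromosome-sizes TSV (`genome.tsv`) and the truth
#' table (`truth.tsv`).
#'
#' @param sim a `sim_cohort` from [simulate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim_cohort <- function(sim, dir) {
  dir.create(file.path(dir, "calls"), recursive = TRUE,
             showWarnings = FALSE)
  paths <- character(nrow(sim$samples))
  for (s in seq_len(nrow(sim$samples))) {
    sid <- sim$samples$sample_id[[s]]
    sub <- sim$calls[sim$calls$sample_id == sid, , drop = FALSE]
    lines <- sprintf("%s\t%s:%d-%d\t%d\t%.6f\t0\t0\t0\t0\t0",
                     ifelse(sub$cnv_type == "DEL", "deletion",
                            "duplication"),
                     sub$chrom, as.integer(sub$start), as.integer(sub$end),
                     as.integer(sub$end - sub$start),
                     sub$copy_number / 2)
    p <- file.path(dir, "calls", paste0(sid, ".txt"))
    writeLines(lines, p)
    # sheet paths are relative to the sheet so the output tree relocates
    paths[[s]] <- file.path("calls", paste0(sid, ".txt"))
  }
  sheet <- cbind(sim$samples, path = paths, format = "cnvnator")
  utils::write.table(sheet, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_chrom_sizes(sim$genome, file.path(dir, "genome.tsv"))
  utils::write.table(sim$truth$loci, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Match cohort CNVRs to planted loci by reciprocal overlap
#'
#' @param cnvrs a `cnvr_set` or CNVR data.frame.
#' @param loci truth locus data.frame (`locus_id`, `chrom`, `start`,
#'   `end`).
#' @param frac reciprocal-overlap threshold (default 0.5).
#' @return data.frame `cnvr_id`, `locus_id` with one row per matched pair.
#' @export
match_cnvrs_to_loci <- function(cnvrs, loci, frac = 0.5) {
  df <- if (inherits(cnvrs, "cnvr_set")) cnvrs$cnvrs else cnvrs
  empty <- data.frame(cnvr_id = character(), locus_id = character(),
                      stringsAsFactors = FALSE)
  if (nrow(df) == 0L || nrow(loci) == 0L) return(empty)
  hits <- GenomicRanges::findOverlaps(.as_granges(df), .as_granges(loci))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (length(qi) == 0L) return(empty)
  ov <- .ov_len(df$start[qi], df$end[qi], loci$start[si], loci$end[si])
  ok <- ov / (df$end[qi] - df$start[qi]) >= frac &
        ov / (loci$end[si] - loci$start[si]) >= frac
  out <- data.frame(cnvr_id = df$cnvr_id[qi[ok]],
                    locus_id = loci$locus_id[si[ok]],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "sim_cohort: %d samples in %d populations, %d loci (%d differentiated), %d calls\n",
    nrow(x$samples), length(x$config$populations), nrow(x$truth$loci),
    sum(x$truth$loci$differentiated), nrow(x$calls)))
  invisible(x)
}
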