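#' Simulation configuration for the three-group heat-stress design
#'
#' Defines the synthetic negative-binomial dataset the package uses for
#' parameter-recovery testing: three groups (NC, HS, PF) with `n_replicates`
#' samples each, planted heat-specific lncRNAs (fold change `heat_fc` in HS
#' only), feed-confounded lncRNAs (fold change `feed_fc` shared by HS and PF,
#' emulating reduced feed intake), and planted ceRNA triplets whose members
#' share a per-sample latent activity (added to the lncRNA and mRNA log-means,
#' subtracted from the miRNA log-mean).
#'
#' Defaults describe lowly expressed lncRNA-scale features (`baseline_mean`
#' 50 expected counts, dispersion 0.1) while planted triplet members are
#' modelled as highly expressed, tightly co-regulated genes
#' (`triplet_mean` 400, `triplet_dispersion` 0.005): the Pearson > 0.9
#' co-expression threshold downstream is only attainable when shared
#' regulation dominates residual noise.
#'
#' @param n_replicates samples per group (default 6, the study design).
#' @param n_lncRNA,n_miRNA,n_mRNA number of features per class.
#' @param baseline_mean expected count of an unperturbed feature.
#' @param dispersion negative-binomial dispersion (1/size) shared per class.
#' @param n_planted_de_lnc number of heat-specific lncRNAs (fold change in HS
#'   only); 70% are up-regulated, the rest down.
#' @param heat_fc fold change of planted heat lncRNAs in HS (must differ from
#'   1 when any are planted).
#' @param n_planted_feed_lnc number of feed-confounded lncRNAs (fold change in
#'   both HS and PF vs NC; half up, half down).
#' @param feed_fc shared HS/PF fold change of feed-confounded lncRNAs.
#' @param n_planted_triplets number of planted lncRNA-miRNA-mRNA triplets; the
#'   lncRNA members are drawn from the planted heat-specific set (when
#'   available) so the full screen can recover them.
#' @param latent_sd SD (log2 units) of the per-sample shared latent activity
#'   coupling triplet members.
#' @param triplet_noise_sd SD (log2 units) of member-specific noise on top of
#'   the shared activity.
#' @param triplet_mean,triplet_dispersion NB mean and dispersion of triplet
#'   member features.
#' @param depth_jitter library sizes are scaled uniformly within
#'   `1 +/- depth_jitter` so normalization is non-trivial.
#' @param seed integer seed; all randomness flows from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_replicates = 6, n_lncRNA = 300, n_miRNA = 80, n_mRNA = 400,
                       baseline_mean = 50, dispersion = 0.1,
                       n_planted_de_lnc = 20, heat_fc = 2.5,
                       n_planted_feed_lnc = 20, feed_fc = 1.8,
                       n_planted_triplets = 10, latent_sd = 0.5,
                       triplet_noise_sd = 0.1, triplet_mean = 400,
                       triplet_dispersion = 0.005, depth_jitter = 0.2, seed = 1L) {
  check_scalar(n_replicates, "n_replicates", "count")
  if (n_replicates < 2) stop("configuration error: 'n_replicates' must be >= 2", call. = FALSE)
  check_scalar(n_lncRNA, "n_lncRNA", "count")
  check_scalar(n_miRNA, "n_miRNA", "count")
  check_scalar(n_mRNA, "n_mRNA", "count")
  check_scalar(baseline_mean, "baseline_mean", "positive")
  check_scalar(dispersion, "dispersion", "positive")
  check_scalar(n_planted_de_lnc, "n_planted_de_lnc", "count")
  check_scalar(heat_fc, "heat_fc", "positive")
  check_scalar(n_planted_feed_lnc, "n_planted_feed_lnc", "count")
  check_scalar(feed_fc, "feed_fc", "positive")
  check_scalar(n_planted_triplets, "n_planted_triplets", "count")
  check_scalar(latent_sd, "latent_sd", "nonneg")
  check_scalar(triplet_noise_sd, "triplet_noise_sd", "nonneg")
  check_scalar(triplet_mean, "triplet_mean", "positive")
  check_scalar(triplet_dispersion, "triplet_dispersion", "positive")
  check_scalar(depth_jitter, "depth_jitter", "nonneg")
  if (depth_jitter >= 1) stop("configuration error: 'depth_jitter' must be < 1", call. = FALSE)
  check_scalar(seed, "seed", "real")
  if (n_planted_de_lnc > n_lncRNA) {
    stop("configuration error: 'n_planted_de_lnc' exceeds 'n_lncRNA'", call. = FALSE)
  }
  if (n_planted_de_lnc + n_planted_feed_lnc > n_lncRNA) {
    stop("configuration error: planted lncRNAs exceed 'n_lncRNA'", call. = FALSE)
  }
  if (n_planted_triplets > min(n_lncRNA, n_miRNA, n_mRNA)) {
    stop("configuration error: 'n_planted_triplets' exceeds a feature-class size",
         call. = FALSE)
  }
  if (heat_fc == 1 && n_planted_de_lnc > 0) {
    stop("configuration error: 'heat_fc' must differ from 1 when heat lncRNAs are planted",
         call. = FALSE)
  }
  structure(list(n_replicates = n_replicates, n_lncRNA = n_lncRNA,
                 n_miRNA = n_miRNA, n_mRNA = n_mRNA,
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 n_planted_de_lnc = n_planted_de_lnc, heat_fc = heat_fc,
                 n_planted_feed_lnc = n_planted_feed_lnc, feed_fc = feed_fc,
                 n_planted_triplets = n_planted_triplets, latent_sd = latent_sd,
                 triplet_noise_sd = triplet_noise_sd, triplet_mean = triplet_mean,
                 triplet_dispersion = triplet_dispersion,
                 depth_jitter = depth_jitter, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic three-group heat-stress dataset
#'
#' Draws negative-binomial count matrices for lncRNAs, miRNAs and mRNAs over
#' 3 x `n_replicates` samples with the structure described in [sim_config()],
#' plus a ground-truth ledger for parameter-recovery tests. The same seed
#' produces identical output.
#'
#' @param config a [sim_config()].
#' @return a list of class `chs_simulation` with elements `lncRNA`, `miRNA`,
#'   `mRNA` ([expression_matrix()] objects with lengths), `design`
#'   ([sample_design()]), `truth` (list: `heat_specific` data.frame
#'   feature/direction, `feed_confounded` data.frame, `triplets` data.frame
#'   lncRNA/miRNA/mRNA/direction) and `config`.
#' @export
simulate_chs_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    nrep <- config$n_replicates
    groups <- rep(c("NC", "HS", "PF"), each = nrep)
    samples <- paste0(groups, "_", rep(seq_len(nrep), 3))
    design <- sample_design(samples, groups, rep(seq_len(nrep), 3))
    ns <- length(samples)
    lib <- stats::runif(ns, 1 - config$depth_jitter, 1 + config$depth_jitter)
    hs <- groups == "HS"
    pf <- groups == "PF"

    ids <- list(lncRNA = sprintf("lnc_%03d", seq_len(config$n_lncRNA)),
                miRNA  = sprintf("mir_%03d", seq_len(config$n_miRNA)),
                mRNA   = sprintf("mrna_%03d", seq_len(config$n_mRNA)))

    # planted assignments
    heat_ids <- if (config$n_planted_de_lnc > 0)
      sort(sample(ids$lncRNA, config$n_planted_de_lnc)) else character(0)
    n_up <- ceiling(0.7 * length(heat_ids))
    heat_dir <- rep(c(1, -1), c(n_up, length(heat_ids) - n_up))
    feed_pool <- setdiff(ids$lncRNA, heat_ids)
    feed_ids <- if (config$n_planted_feed_lnc > 0)
      sort(sample(feed_pool, config$n_planted_feed_lnc)) else character(0)
    feed_dir <- rep_len(c(1, -1), length(feed_ids))

    nt <- config$n_planted_triplets
    trip_lnc <- character(0); trip_dir <- integer(0)
    if (nt > 0) {
      from_heat <- min(nt, length(heat_ids))
      trip_lnc <- heat_ids[seq_len(from_heat)]
      trip_dir <- heat_dir[seq_len(from_heat)]
      if (from_heat < nt) {   # no (or too few) heat lncRNAs: pure correlation plants
        extra <- sample(setdiff(ids$lncRNA, c(heat_ids, feed_ids)), nt - from_heat)
        trip_lnc <- c(trip_lnc, extra)
        trip_dir <- c(trip_dir, rep(0L, nt - from_heat))
      }
    }
    trip_mir <- if (nt > 0) sample(ids$miRNA, nt) else character(0)
    trip_mrna <- if (nt > 0) sample(ids$mRNA, nt) else character(0)

    draw_class <- function(fids) {
      base <- stats::rlnorm(length(fids), meanlog = log(config$baseline_mean), sdlog = 0.5)
      mu <- matrix(base, nrow = length(fids), ncol = ns,
                   dimnames = list(fids, samples))
      list(mu = mu, size = rep(1 / config$dispersion, length(fids)))
    }
    lnc <- draw_class(ids$lncRNA)
    mir <- draw_class(ids$miRNA)
    mrna <- draw_class(ids$mRNA)

    # heat-specific lncRNAs: fold change in HS only
    if (length(heat_ids)) {
      fcs <- config$heat_fc^heat_dir
      lnc$mu[heat_ids, hs] <- lnc$mu[heat_ids, hs] * fcs
    }
    # feed-confounded lncRNAs: shared HS/PF fold change
    if (length(feed_ids)) {
      fcs <- config$feed_fc^feed_dir
      lnc$mu[feed_ids, hs | pf] <- lnc$mu[feed_ids, hs | pf] * fcs
    }
    # planted triplets: shared latent activity (heat shift + per-sample noise)
    if (nt > 0) {
      log2_heat <- log2(config$heat_fc)
      for (t in seq_len(nt)) {
        a <- trip_dir[t] * log2_heat * as.numeric(hs) +
          stats::rnorm(ns, 0, config$latent_sd)
        member <- function() {
          config$triplet_mean *
            2^(stats::rnorm(ns, 0, config$triplet_noise_sd))
        }
        lnc$mu[trip_lnc[t], ] <- member() * 2^a
        mrna$mu[trip_mrna[t], ] <- member() * 2^a
        mir$mu[trip_mir[t], ] <- member() * 2^(-a)
        lnc$size[match(trip_lnc[t], ids$lncRNA)] <- 1 / config$triplet_dispersion
        mrna$size[match(trip_mrna[t], ids$mRNA)] <- 1 / config$triplet_dispersion
        mir$size[match(trip_mir[t], ids$miRNA)] <- 1 / config$triplet_dispersion
      }
    }

    nb_counts <- function(cl) {
      mu <- sweep(cl$mu, 2, lib, "*")
      cnt <- matrix(stats::rnbinom(length(mu), mu = as.numeric(mu),
                                   size = rep(cl$size, times = ncol(mu))),
                    nrow = nrow(mu), dimnames = dimnames(mu))
      cnt
    }
    len <- list(lncRNA = round(stats::runif(config$n_lncRNA, 200, 3000)),
                miRNA = round(stats::runif(config$n_miRNA, 20, 24)),
                mRNA = round(stats::runif(config$n_mRNA, 500, 5000)))
    mk <- function(cl, class, lens) {
      names(lens) <- rownames(cl$mu)
      expression_matrix(nb_counts(cl), class, lengths = lens)
    }
    out <- list(
      lncRNA = mk(lnc, "lncRNA", len$lncRNA),
      miRNA = mk(mir, "miRNA", len$miRNA),
      mRNA = mk(mrna, "mRNA", len$mRNA),
      design = design,
      truth = list(
        heat_specific = data.frame(feature = heat_ids,
                                   direction = ifelse(heat_dir > 0, "up", "down"),
                                   stringsAsFactors = FALSE),
        feed_confounded = data.frame(feature = feed_ids,
                                     direction = ifelse(feed_dir > 0, "up", "down"),
                                     stringsAsFactors = FALSE),
        triplets = data.frame(lncRNA = trip_lnc, miRNA = trip_mir, mRNA = trip_mrna,
                              direction = ifelse(trip_dir > 0, "up",
                                                 ifelse(trip_dir < 0, "down", "none")),
                              stringsAsFactors = FALSE)
      ),
      config = config)
    class(out) <- "chs_simulation"
    out
  })
}

#' @export
print.chs_simulation <- function(x, ...) {
  cat(sprintf("<chs_simulation> %d lncRNA / %d miRNA / %d mRNA x %d samples\n",
              nrow(x$lncRNA$values), nrow(x$miRNA$values), nrow(x$mRNA$values),
              nrow(x$design)))
  cat(sprintf("  planted: %d heat-specific, %d feed-confounded lncRNAs, %d triplets\n",
              nrow(x$truth$heat_specific), nrow(x$truth$feed_confounded),
              nrow(x$truth$triplets)))
  invisible(x)
}

#' Generate candidate miRNA-target pairs from a simulation's ground truth
#'
#' Emits all miRNA-lncRNA and miRNA-mRNA pairs implied by the planted
#' triplets plus `n_decoys` random non-planted pairs, standing in for
#' sequence-based target prediction output.
#'
#' @param sim a `chs_simulation` (its truth and feature universes are used).
#' @param n_decoys number of additional unique random pairs (default 200).
#' @param seed integer seed for the decoy draw.
#' @return a `data.frame` (class `target_pairs`) with columns `miRNA`,
#'   `partner_id`, `partner_class`; no duplicate rows.
#' @export
generate_target_pairs <- function(sim, n_decoys = 200, seed = 1L) {
  stopifnot(inherits(sim, "chs_simulation"))
  check_scalar(n_decoys, "n_decoys", "count")
  tr <- sim$truth$triplets
  planted <- rbind(
    data.frame(miRNA = tr$miRNA, partner_id = tr$lncRNA, partner_class = "lncRNA",
               stringsAsFactors = FALSE),
    data.frame(miRNA = tr$miRNA, partner_id = tr$mRNA, partner_class = "mRNA",
               stringsAsFactors = FALSE))
  mirs <- rownames(sim$miRNA$values)
  partners <- data.frame(
    partner_id = c(rownames(sim$lncRNA$values), rownames(sim$mRNA$values)),
    partner_class = rep(c("lncRNA", "mRNA"),
                        c(nrow(sim$lncRNA$values), nrow(sim$mRNA$values))),
    stringsAsFactors = FALSE)
  out <- planted
  if (n_decoys > 0) {
    with_seed(seed, {
      seen <- paste(out$miRNA, out$partner_id)
      need <- n_decoys
      while (need > 0) {
        mi <- sample(mirs, need, replace = TRUE)
        pi <- sample(nrow(partners), need, replace = TRUE)
        cand <- data.frame(miRNA = mi, partner_id = partners$partner_id[pi],
                           partner_class = partners$partner_class[pi],
                           stringsAsFactors = FALSE)
        key <- paste(cand$miRNA, cand$partner_id)
        keep <- !(key %in% seen) & !duplicated(key)
        cand <- cand[keep, , drop = FALSE]
        seen <- c(seen, key[keep])
        out <- rbind(out, cand)
        need <- n_decoys + nrow(planted) - nrow(out)
      }
    })
  }
  rownames(out) <- NULL
  class(out) <- c("target_pairs", "data.frame")
  out
}
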