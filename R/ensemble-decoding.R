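#' Build a trial x bin x unit rate matrix
#'
#' Bins each unit's spikes in 100 ms bins over a 0-1 s window aligned to
#' an event per trial (odor onset or port exit), scaled to Hz. Sessions
#' with fewer than `min_units` task-responsive units are skipped (error of
#' class `session_skip`).
#'
#' @param units List of [spike_train()]s (the task-responsive set).
#' @param trials A [trial_table()].
#' @param alignment `"odor_on"` (port_in) or `"port_out"`.
#' @param window_s Window length (s).
#' @param bin_s Bin width (s).
#' @param min_units Minimum number of units (default 4).
#' @return A list of class `rate_matrix` with `values` (array trials x
#'   bins x units, Hz), `units` (ids), `trial_id`, `choice`, `correct`,
#'   `bin_edges`, `alignment`.
#' @export
build_rate_matrix <- function(units, trials, alignment = c("odor_on", "port_out"),
                              window_s = 1, bin_s = 0.1, min_units = 4) {
  alignment <- match.arg(alignment)
  if (length(units) < min_units) {
    abort(sprintf("Only %d units (< %d); session skipped.",
                  length(units), min_units),
          class = "session_skip")
  }
  inc <- included_trials(trials)
  t0 <- if (alignment == "odor_on") inc$port_in else inc$port_out
  nbin <- round(window_s / bin_s)
  edges <- (0:nbin) * bin_s
  vals <- array(0, dim = c(nrow(inc), nbin, length(units)))
  for (ui in seq_along(units)) {
    st <- units[[ui]]$spike_times
    for (k in seq_len(nrow(inc))) {
      rel <- st[st >= t0[k] & st < t0[k] + window_s] - t0[k]
      if (length(rel) == 0) next
      h <- findInterval(rel, edges, rightmost.closed = FALSE)
      h <- h[h >= 1 & h <= nbin]
      cnt <- tabulate(h, nbins = nbin)
      vals[k, , ui] <- cnt / bin_s
    }
  }
  structure(list(values = vals,
                 units = vapply(units, function(u) u$unit_id, integer(1)),
                 trial_id = inc$trial_id, choice = inc$choice,
                 correct = inc$correct, bin_edges = edges,
                 alignment = alignment),
            class = "rate_matrix")
}

# Flatten the rate array to (trial*bin) x unit observations.
rm_flat <- function(rm) {
  d <- dim(rm$values)
  matrix(aperm(rm$values, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
}

#' PCA trajectory discrimination
#'
#' Fits PCA on the pooled trial x bin population activity (bins as
#' observations), projects the per-choice mean trajectories onto the
#' first `n_pc` PCs, and computes the per-bin Euclidean distance between
#' the left- and right-choice mean trajectories. The null shuffles choice
#' labels across trials and recomputes the distance; the discrimination
#' time is the first bin at which the real distance exceeds the pointwise
#' 95th percentile of the null. An even/odd control splits trials within
#' each choice and averages the two within-choice distances.
#'
#' @param rm A [build_rate_matrix()] result.
#' @param n_pc Number of principal components (default 3).
#' @param n_shuffle Number of label shuffles.
#' @return A list of class `trajectory_discrimination` with `dist`,
#'   `null_ci95`, `evenodd_dist` (per-bin), `discrimination_time_s`
#'   (`NA` when never exceeded), `bin_centers_s`, `pc_coords`.
#' @export
pca_discrimination <- function(rm, n_pc = 3, n_shuffle = 500) {
  labels <- rm$choice
  if (min(table(factor(labels, levels = 1:2))) < 5) {
    abort("Both choices need at least 5 trials.")
  }
  d <- dim(rm$values)
  X <- rm_flat(rm)
  rk <- qr(scale(X, scale = FALSE))$rank
  if (rk < n_pc) {
    warn(sprintf("Data rank %d < %d PCs; using %d.", rk, n_pc, rk))
    n_pc <- rk
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  W <- pc$rotation[, seq_len(n_pc), drop = FALSE]
  ctr <- pc$center

  proj_traj <- function(lab_sel) {
    mt <- apply(rm$values[lab_sel, , , drop = FALSE], c(2, 3), mean)
    sweep(mt, 2, ctr) %*% W            # bins x n_pc
  }
  dist_for <- function(labels) {
    a <- proj_traj(labels == 1)
    b <- proj_traj(labels == 2)
    sqrt(rowSums((a - b)^2))
  }
  dist <- dist_for(labels)
  null <- matrix(NA_real_, n_shuffle, d[2])
  for (s in seq_len(n_shuffle)) {
    null[s, ] <- dist_for(sample(labels))
  }
  ci95 <- apply(null, 2, quantile, probs = 0.95)

  # even/odd control: distance between half-sample means within a choice.
  # Half-sample means carry twice the variance of the full-class means the
  # shuffle null uses, so the distance is scaled by 1/sqrt(2) to sit on the
  # same noise footing (balanced classes assumed).
  eo <- function(lab) {
    idx <- which(labels == lab)
    even <- idx[seq_along(idx) %% 2 == 0]
    odd <- idx[seq_along(idx) %% 2 == 1]
    a <- proj_traj(seq_len(d[1]) %in% even)
    b <- proj_traj(seq_len(d[1]) %in% odd)
    sqrt(rowSums((a - b)^2))
  }
  evenodd <- (eo(1) + eo(2)) / (2 * sqrt(2))

  exceed <- which(dist > ci95)
  centers <- (rm$bin_edges[-1] + rm$bin_edges[-length(rm$bin_edges)]) / 2
  disc_t <- if (length(exceed)) centers[min(exceed)] else NA_real_
  structure(list(dist = dist, null_ci95 = ci95, evenodd_dist = evenodd,
                 discrimination_time_s = disc_t, bin_centers_s = centers,
                 pc_coords = list(left = proj_traj(labels == 1),
                                  right = proj_traj(labels == 2)),
                 n_pc = n_pc),
            class = "trajectory_discrimination")
}

# Stratified k-fold partition of trial indices by label.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (lab in unique(labels)) {
    idx <- sample(which(labels == lab))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' GLM choice prediction over cumulative windows
#'
#' Predicts the upcoming choice from per-unit spike counts in cumulative
#' windows 0-0.1 s, 0-0.2 s, ..., 0-1.0 s from the alignment event, with a
#' binomial GLM and stratified five-fold cross-validation. Accuracy is
#' correctly predicted / tested trials averaged over folds. The null
#' repeats the procedure with shuffled choice labels; a rank-sum test
#' compares the real per-fold accuracies against the null accuracies per
#' window. The default link is logit; `link = "log"` fits a log-binomial
#' model instead (falling back to logit if it fails to converge).
#'
#' @param rm A [build_rate_matrix()] result (bin width 0.1 s).
#' @param k Number of folds.
#' @param n_shuffle Number of label-shuffled null repetitions.
#' @param windows_s Cumulative window ends (s).
#' @param link `"logit"` or `"log"`.
#' @return A tibble of class `glm_prediction` with one row per window:
#'   `window_s`, `accuracy`, `null_mean`, `p`, and per-fold accuracies in
#'   `attr(, "folds")`.
#' @export
glm_choice_prediction <- function(rm, k = 5, n_shuffle = 20,
                                  windows_s = seq(0.1, 1, by = 0.1),
                                  link = c("logit", "log")) {
  link <- match.arg(link)
  labels <- rm$choice
  n_tr <- length(labels)
  if (n_tr < 20) abort("At least 20 trials are required.")
  d <- dim(rm$values)
  bin_ends <- rm$bin_edges[-1]

  fit_acc <- function(counts, y, fold) {
    acc <- numeric(k)
    for (f in seq_len(k)) {
      tr <- fold != f
      dftr <- data.frame(y = y[tr], counts[tr, , drop = FALSE])
      dfte <- data.frame(counts[!tr, , drop = FALSE])
      fam <- if (link == "logit") stats::binomial("logit") else
        stats::binomial("log")
      fit <- tryCatch(
        suppressWarnings(glm(y ~ ., data = dftr, family = fam,
                             control = list(maxit = 100))),
        error = function(e) NULL)
      if (is.null(fit) && link == "log") {
        fit <- suppressWarnings(glm(y ~ ., data = dftr,
                                    family = stats::binomial("logit"),
                                    control = list(maxit = 100)))
      }
      pr <- suppressWarnings(predict(fit, newdata = dfte, type = "response"))
      acc[f] <- mean((pr > 0.5) == (y[!tr] == 1))
    }
    acc
  }

  rows <- list()
  fold_list <- list()
  for (w in windows_s) {
    nb <- round(w / 0.1)
    counts <- apply(rm$values[, seq_len(nb), , drop = FALSE], c(1, 3), mean)
    colnames(counts) <- paste0("u", seq_len(ncol(counts)))
    y <- as.integer(labels == 1)
    fold <- stratified_folds(labels, k)
    acc <- fit_acc(counts, y, fold)
    null_acc <- vapply(seq_len(n_shuffle), function(s) {
      ys <- sample(y)
      mean(fit_acc(counts, ys, stratified_folds(ys + 1L, k)))
    }, numeric(1))
    # primary p: permutation of the mean cross-validated accuracy (the
    # observed run is exchangeable with the shuffled runs under the null);
    # the rank-sum of fold accuracies vs null accuracies is reported too,
    # but folds share training data so its nominal level is not reliable
    p_perm <- (1 + sum(null_acc >= mean(acc))) / (1 + n_shuffle)
    p_ranksum <- suppressWarnings(
      wilcox.test(acc, null_acc, alternative = "greater")$p.value)
    rows[[length(rows) + 1]] <- tibble(window_s = w, accuracy = mean(acc),
                                       null_mean = mean(null_acc),
                                       p = p_perm, p_ranksum = p_ranksum)
    fold_list[[length(fold_list) + 1]] <- acc
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "folds") <- fold_list
  class(out) <- c("glm_prediction", class(out))
  out
}

#' Train the memoryless Poisson Bayesian choice decoder
#'
#' Estimates per-unit, per-choice mean rates `f_i(X)` from training
#' trials, with a floor of `eps` Hz so a unit silent for one choice does
#' not zero the likelihood. In odor-period mode the window is
#' `[port_in, port_out)`; in spatial mode the caller supplies per-trial
#' spike counts and occupancy directly (see
#' [decode_choice_by_quintile()]).
#'
#' @param units List of [spike_train()]s.
#' @param trials A [trial_table()] (training trials only).
#' @param eps Rate floor (Hz).
#' @return A list of class `bayes_decoder` with `f` (units x 2 matrix of
#'   rates), `unit_ids`, `n_train` (training trials per choice), `eps`.
#' @export
bayes_train <- function(units, trials, eps = 0.01) {
  inc <- included_trials(trials)
  for (ch in 1:2) {
    if (sum(inc$choice == ch) == 0) {
      abort(sprintf("No training trials for choice %d.", ch))
    }
  }
  f <- matrix(eps, length(units), 2)
  for (ui in seq_along(units)) {
    st <- units[[ui]]$spike_times
    for (ch in 1:2) {
      tr <- inc[inc$choice == ch, , drop = FALSE]
      dur <- sum(tr$port_out - tr$port_in)
      n <- sum(count_in_windows(st, cbind(tr$port_in, tr$port_out)))
      f[ui, ch] <- max(eps, n / dur)
    }
  }
  structure(list(f = f,
                 unit_ids = vapply(units, function(u) u$unit_id, integer(1)),
                 n_train = c(sum(inc$choice == 1), sum(inc$choice == 2)),
                 eps = eps),
            class = "bayes_decoder")
}

#' Decode a choice from spike counts
#'
#' Memoryless Poisson decoding: for each choice X the log-likelihood is
#' `sum_i spikes_i * log f_i(X) - tau * sum_i f_i(X)` (the log of
#' `prod_i f_i(X)^spikes_i * exp(-tau * sum_i f_i(X))` up to the
#' count-factorial constant shared by both choices); the posterior is the
#' softmax over the two choices under a uniform prior. Ties decode to the
#' choice with more training trials.
#'
#' @param decoder A [bayes_train()] result.
#' @param spike_counts Integer vector, one count per unit.
#' @param tau Decoding window duration (s).
#' @return A tibble with `posterior1`, `posterior2`, `decoded`.
#' @export
bayes_decode <- function(decoder, spike_counts, tau) {
  if (tau <= 0) abort("`tau` must be positive.")
  if (any(spike_counts < 0)) abort("Counts must be nonnegative.")
  if (length(spike_counts) != nrow(decoder$f)) {
    abort("One spike count per unit is required.")
  }
  ll <- vapply(1:2, function(ch) {
    sum(spike_counts * log(decoder$f[, ch])) - tau * sum(decoder$f[, ch])
  }, numeric(1))
  ll <- ll - max(ll)
  post <- exp(ll) / sum(exp(ll))
  decoded <- if (abs(post[1] - post[2]) < 1e-12) {
    which.max(decoder$n_train)
  } else {
    which.max(post)
  }
  tibble(posterior1 = post[1], posterior2 = post[2],
         decoded = as.integer(decoded))
}

# Per-trial quintile spike counts and occupancy for run periods.
# Run window: starts 0.5 s after port_out, samples with speed > 3 cm/s.
quintile_occupancy <- function(units, trials, position, linear,
                               route_len, n_q = 5) {
  inc <- included_trials(trials)
  qlen <- route_len / n_q
  dt <- median(diff(position$t))
  n_u <- length(units)
  occ <- array(0, dim = c(nrow(inc), n_q))
  cnt <- array(0L, dim = c(nrow(inc), n_q, n_u))
  for (k in seq_len(nrow(inc))) {
    w0 <- inc$port_out[k] + 0.5
    w1 <- if (!is.na(inc$reward_in[k])) inc$reward_in[k] else w0
    sel <- position$t >= w0 & position$t < w1 & position$speed > 3
    if (!any(sel)) next
    qi <- pmin(n_q, floor(linear[sel] / qlen) + 1)
    for (q in seq_len(n_q)) occ[k, q] <- sum(qi == q) * dt
    tsel <- position$t[sel]
    for (ui in seq_len(n_u)) {
      st <- units[[ui]]$spike_times
      st <- st[st >= w0 & st < w1]
      if (length(st) == 0) next
      # nearest position sample gives the quintile of each spike
      pi_idx <- findInterval(st, tsel)
      ok <- pi_idx >= 1
      qspk <- qi[pmax(pi_idx, 1)]
      for (q in seq_len(n_q)) {
        cnt[k, q, ui] <- cnt[k, q, ui] + sum(ok & qspk == q)
      }
    }
  }
  list(occ = occ, counts = cnt, trials = inc)
}

#' Choice decoding across spatial quintiles
#'
#' Splits the 123 cm linearized outbound route into five equal quintiles
#' (24.6 cm each) and decodes each trial's upcoming choice from the spike
#' counts emitted in each quintile, with `tau` equal to the trial's
#' occupancy of that quintile. Two training modes: `"odor_period"` trains
#' the decoder once on odor-sampling activity; `"spatial_quintile"`
#' trains a separate decoder per quintile from the training trials' run
#' activity in that quintile. Five-fold cross-validation as in the GLM;
#' the p-value per quintile comes from the Gaussian statistics (mean/sd)
#' of `n_shuffle` label-shuffled decoders.
#'
#' @param units List of [spike_train()]s.
#' @param trials A [trial_table()].
#' @param position A [position_trace()].
#' @param linear Per-sample linear position (cm along the outbound route;
#'   e.g. from [linearize_runs()] or the generator's ground truth).
#' @param decoder_mode `"odor_period"` or `"spatial_quintile"`.
#' @param route_len Route length (cm).
#' @param n_shuffle Number of choice-label shuffles (default 200).
#' @param k Folds.
#' @return A tibble of class `quintile_decoding`: per quintile `quintile`,
#'   `accuracy`, `null_mean`, `null_sd`, `p` (one-sided Gaussian),
#'   `n_trials`.
#' @export
decode_choice_by_quintile <- function(units, trials, position, linear,
                                      decoder_mode = c("odor_period",
                                                       "spatial_quintile"),
                                      route_len = 123, n_shuffle = 200,
                                      k = 5) {
  decoder_mode <- match.arg(decoder_mode)
  qo <- quintile_occupancy(units, trials, position, linear, route_len)
  inc <- qo$trials
  n_q <- ncol(qo$occ)
  n_u <- length(units)
  labels <- inc$choice
  eps <- 0.01

  # precompute per-trial, per-unit odor-period spike counts and durations
  odor_dur <- inc$port_out - inc$port_in
  odor_cnt <- vapply(units, function(u) {
    count_in_windows(u$spike_times, cbind(inc$port_in, inc$port_out))
  }, integer(nrow(inc)))                         # trials x units

  run_decode <- function(lab) {
    fold <- stratified_folds(lab, k)
    correct <- matrix(NA, nrow(inc), n_q)
    for (f in seq_len(k)) {
      test <- which(fold == f)
      train <- which(fold != f)
      # f_list[[q]]: units x 2 rate matrix for quintile q
      if (decoder_mode == "odor_period") {
        f_mat <- vapply(1:2, function(ch) {
          rows <- train[lab[train] == ch]
          pmax(eps, colSums(odor_cnt[rows, , drop = FALSE]) /
                 sum(odor_dur[rows]))
        }, numeric(n_u))
        f_list <- rep(list(f_mat), n_q)
      } else {
        f_list <- lapply(seq_len(n_q), function(q) {
          vapply(1:2, function(ch) {
            rows <- train[lab[train] == ch]
            tot_occ <- sum(qo$occ[rows, q])
            if (tot_occ <= 0) return(rep(eps, n_u))
            pmax(eps, colSums(qo$counts[rows, q, , drop = FALSE]) / tot_occ)
          }, numeric(n_u))
        })
      }
      n_tr_ch <- c(sum(lab[train] == 1), sum(lab[train] == 2))
      for (q in seq_len(n_q)) {
        fm <- f_list[[q]]
        lf <- log(fm)
        sf <- colSums(fm)
        for (ti in test) {
          tau <- qo$occ[ti, q]
          if (tau <= 0) next
          ll <- crossprod(qo$counts[ti, q, ], lf) - tau * sf
          decoded <- if (abs(ll[1] - ll[2]) < 1e-12) {
            which.max(n_tr_ch)
          } else {
            which.max(ll)
          }
          correct[ti, q] <- decoded == labels[ti]
        }
      }
    }
    colMeans(correct, na.rm = TRUE)
  }

  obs <- run_decode(labels)
  null <- matrix(NA_real_, n_shuffle, n_q)
  for (s in seq_len(n_shuffle)) {
    null[s, ] <- run_decode(sample(labels))
  }
  nm <- colMeans(null, na.rm = TRUE)
  nsd <- apply(null, 2, sd, na.rm = TRUE)
  p <- pnorm((obs - nm) / pmax(nsd, 1e-12), lower.tail = FALSE)
  out <- tibble(quintile = seq_len(n_q), accuracy = obs, null_mean = nm,
                null_sd = nsd, p = p,
                n_trials = colSums(qo$occ > 0))
  class(out) <- c("quintile_decoding", class(out))
  out
}
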