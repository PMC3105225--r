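# Independent oracles and fixture builders used across the suite.
# These are deliberately naive re-statements of the definitions, coded
# differently from the package internals.

# Brute-force max-interval scan: explicit state machine over spikes, repeated
# pairwise merging, then filtering.
oracle_max_interval <- function(t, cfg) {
  n <- length(t)
  cand <- list()
  i <- 1L
  while (i < n) {
    if (t[i + 1L] - t[i] <= cfg$max_isi_start) {
      j <- i + 1L
      while (j < n && t[j + 1L] - t[j] <= cfg$max_isi_end) j <- j + 1L
      cand[[length(cand) + 1L]] <- c(i, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(cand) > 1L) {
    merged <- list(cand[[1L]])
    for (k in 2:length(cand)) {
      prev <- merged[[length(merged)]]
      if (t[cand[[k]][1L]] - t[prev[2L]] < cfg$min_ibi_merge) {
        merged[[length(merged)]] <- c(prev[1L], cand[[k]][2L])
      } else {
        merged[[length(merged) + 1L]] <- cand[[k]]
      }
    }
    cand <- merged
  }
  rows <- do.call(rbind, cand)
  if (is.null(rows)) {
    return(data.frame(start = numeric(), end = numeric(),
                      n_spikes = integer(), duration = numeric(),
                      first_spike = integer(), last_spike = integer()))
  }
  dur <- t[rows[, 2L]] - t[rows[, 1L]]
  nsp <- rows[, 2L] - rows[, 1L] + 1L
  keep <- dur >= cfg$min_burst_duration & nsp >= cfg$min_spikes_in_burst
  data.frame(start = t[rows[, 1L]][keep], end = t[rows[, 2L]][keep],
             n_spikes = as.integer(nsp[keep]), duration = dur[keep],
             first_spike = as.integer(rows[, 1L][keep]),
             last_spike = as.integer(rows[, 2L][keep]))
}

# Hand sum-of-squares one-way ANOVA.
oracle_anova <- function(groups) {
  y <- unlist(groups, use.names = FALSE)
  k <- length(groups)
  N <- length(y)
  gm <- mean(y)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, numeric(1)) - gm)^2)
  ssw <- sum(unlist(lapply(groups, function(g) (g - mean(g))^2)))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = f, df_between = k - 1, df_within = N - k, mse = ssw / (N - k),
       p = stats::pf(f, k - 1, N - k, lower.tail = FALSE))
}

# O(n^2) coincidence count.
oracle_ci <- function(a, b, dt, T) {
  nab <- sum(abs(outer(a, b, `-`)) <= dt)
  nab * T / (length(a) * length(b) * 2 * dt)
}

# Random spike trains for property tests: tonic Poisson or burst-structured.
rand_train <- function(kind = c("poisson", "bursty"), T = 60) {
  kind <- match.arg(kind)
  if (kind == "poisson") {
    t <- sort(runif(rpois(1, runif(1, 0.5, 4) * T), 0, T))
  } else {
    onsets <- sort(runif(rpois(1, runif(1, 2, 20)), 0, T))
    t <- unlist(lapply(onsets, function(o) {
      o + cumsum(c(0, rexp(sample(1:12, 1), rate = 1 / runif(1, 0.01, 0.1))))
    }))
    t <- sort(c(t, runif(rpois(1, 0.3 * T), 0, T)))
    t <- t[t >= 0 & t <= T]
  }
  if (length(t) > 1L) t <- t[c(TRUE, diff(t) > 1e-9)]
  t
}

rand_burst_cfg <- function() {
  s <- runif(1, 0.05, 0.3)
  burst_config(max_isi_start = s, max_isi_end = s * runif(1, 1, 2.5),
               min_ibi_merge = runif(1, 0.05, 0.6),
               min_burst_duration = runif(1, 0.001, 0.05),
               min_spikes_in_burst = sample(2:5, 1))
}

# Small-n recording builder: spikes is a named list of time vectors.
make_recording <- function(spikes, epoch_duration = 900, ...) {
  ids <- names(spikes)
  lay <- mea_layout(ids, cbind(row = seq_along(ids), col = 1L))
  trains <- Map(function(id, ts) spike_train(id, ts, epoch_duration),
                ids, spikes)
  mea_recording(unname(trains), layout = lay,
                epoch_duration = epoch_duration, ...)
}
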