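# Independent loop-based oracles used to check the vectorized
# implementations. These deliberately re-derive each quantity from its
# definition with explicit loops and sorting, sharing no code with R/.

# TMM factor for one sample vs a reference, straight from the definition:
# M/A over doubly positive genes, double quantile-rank trim, inverse
# delta-method-variance weighted mean of the surviving M values.
oracle_tmm_one <- function(obs, ref, lib_obs, lib_ref, trim_M = 0.30, trim_A = 0.05) {
  M <- c(); A <- c(); o <- c(); r <- c()
  for (g in seq_along(obs)) {
    if (obs[g] > 0 && ref[g] > 0) {
      m <- log2((obs[g] / lib_obs) / (ref[g] / lib_ref))
      a <- 0.5 * log2((obs[g] / lib_obs) * (ref[g] / lib_ref))
      if (is.finite(m) && is.finite(a)) {
        M <- c(M, m); A <- c(A, a); o <- c(o, obs[g]); r <- c(r, ref[g])
      }
    }
  }
  n <- length(M)
  if (max(abs(M)) < 1e-6) return(1)
  # rank by sorted position (ties by original order = ties.method "first")
  rank_first <- function(x) {
    ord <- order(x, seq_along(x))
    rk <- integer(n)
    for (i in seq_len(n)) rk[ord[i]] <- i
    rk
  }
  rM <- rank_first(M); rA <- rank_first(A)
  loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
  num <- 0; den <- 0; any_kept <- FALSE
  for (i in seq_len(n)) {
    if (rM[i] >= loM && rM[i] <= hiM && rA[i] >= loA && rA[i] <= hiA) {
      w <- (lib_obs - o[i]) / (lib_obs * o[i]) + (lib_ref - r[i]) / (lib_ref * r[i])
      num <- num + M[i] / w
      den <- den + 1 / w
      any_kept <- TRUE
    }
  }
  if (!any_kept) {
    for (i in seq_len(n)) {
      w <- (lib_obs - o[i]) / (lib_obs * o[i]) + (lib_ref - r[i]) / (lib_ref * r[i])
      num <- num + M[i] / w; den <- den + 1 / w
    }
  }
  2^(num / den)
}

oracle_tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  lib <- colSums(counts)
  q75 <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    q75[j] <- quantile(counts[, j] / lib[j], 0.75)
  }
  ref <- which.min(abs(q75 - mean(q75)))
  f <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    f[j] <- if (j == ref) 1 else
      oracle_tmm_one(counts[, j], counts[, ref], lib[j], lib[ref], trim_M, trim_A)
  }
  f / exp(mean(log(f)))
}

# Rank score by explicit sorting and averaging: ascending ranks with
# average ties, mean rank of the set, min-max normalized and centred.
oracle_rank_score <- function(values, set_idx) {
  N <- length(values)
  ord <- order(values)
  ranks <- numeric(N)
  i <- 1
  while (i <= N) {
    j <- i
    while (j < N && values[ord[j + 1]] == values[ord[i]]) j <- j + 1
    avg <- mean(i:j)
    for (k in i:j) ranks[ord[k]] <- avg
    i <- j + 1
  }
  n <- length(set_idx)
  mr <- 0
  for (k in set_idx) mr <- mr + ranks[k]
  mr <- mr / n
  lo <- (n + 1) / 2
  hi <- (2 * N - n + 1) / 2
  (mr - lo) / (hi - lo) - 0.5
}

# Enrichment score by the explicit walk down the ranked list.
oracle_es_walk <- function(stats_sorted_desc, is_hit, weight_p = 1) {
  N <- length(stats_sorted_desc)
  n <- sum(is_hit)
  denom <- 0
  for (i in seq_len(N)) if (is_hit[i]) denom <- denom + abs(stats_sorted_desc[i])^weight_p
  running <- 0
  best_pos <- 0
  best_neg <- 0
  for (i in seq_len(N)) {
    if (is_hit[i]) {
      inc <- if (denom == 0) 1 / n else abs(stats_sorted_desc[i])^weight_p / denom
      running <- running + inc
    } else {
      running <- running - 1 / (N - n)
    }
    if (running > best_pos) best_pos <- running
    if (running < best_neg) best_neg <- running
  }
  # positive extremum on (numerical) ties
  if (abs(best_pos) >= abs(best_neg) - 1e-12) best_pos else best_neg
}

# Adjusted Rand index between two labelings (contingency-table formula).
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  (sij - expected) / (maxi - expected)
}

precision_of <- function(got, want) if (length(got) == 0) NA_real_ else mean(got %in% want)
recall_of <- function(got, want) if (length(want) == 0) NA_real_ else mean(want %in% got)
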