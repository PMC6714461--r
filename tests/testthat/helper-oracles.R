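# Independent oracles used across the suite. These deliberately use naive
# brute-force algorithms, closed forms or exhaustive enumeration, and never
# call the implementation they check.

# exact two-sided rank-sum p by enumeration over all C(n, n1) assignments
oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# brute-force run-length scanner for signal tracks
oracle_call_regions <- function(pos, z, thr, min_run) {
  out <- NULL
  i <- 1L
  n <- length(pos)
  while (i <= n) {
    if (z[i] > thr) {
      j <- i
      while (j < n && z[j + 1L] > thr && pos[j + 1L] == pos[j] + 1L) j <- j + 1L
      if (pos[j] - pos[i] + 1L >= min_run) {
        peak <- i + which.max(z[i:j]) - 1L
        out <- rbind(out, c(pos[peak], pos[i], pos[j]))
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# maximum-cardinality bipartite matching within a window (augmenting paths)
oracle_max_matching <- function(pred_pos, snp_pos, window) {
  adj <- lapply(pred_pos, function(p) which(abs(snp_pos - p) <= window))
  env <- new.env()
  env$match_s <- rep(NA_integer_, length(snp_pos))
  try_augment <- function(i) {
    for (j in adj[[i]]) {
      if (!env$seen[j]) {
        env$seen[j] <- TRUE
        if (is.na(env$match_s[j]) || try_augment(env$match_s[j])) {
          env$match_s[j] <- i
          return(TRUE)
        }
      }
    }
    FALSE
  }
  n_matched <- 0L
  for (i in seq_along(pred_pos)) {
    env$seen <- rep(FALSE, length(snp_pos))
    if (length(adj[[i]]) && try_augment(i)) n_matched <- n_matched + 1L
  }
  n_matched
}

# brute-force single-linkage clustering at a gap threshold
oracle_cluster <- function(chrom, pos, max_gap) {
  o <- order(chrom, pos)
  chrom <- chrom[o]; pos <- pos[o]
  grp <- integer(length(pos))
  g <- 0L
  for (i in seq_along(pos)) {
    if (i == 1L || chrom[i] != chrom[i - 1L] || pos[i] - pos[i - 1L] > max_gap)
      g <- g + 1L
    grp[i] <- g
  }
  tapply(pos, grp, function(p) c(min(p), max(p), length(p)))
}

# closed-form crossing time of a logistic curve at fraction x of its own max
oracle_logistic_tx <- function(frac_of_max, co2_max, t_mid, k, target) {
  # time when co2_max/(1+exp(-k(t-t_mid))) = target
  t_mid - log(co2_max / target - 1) / k
}

# exact type-I rate of the 1-df 1:1 segregation chi-square at n calls
oracle_chisq_type1 <- function(n, alpha = 0.05) {
  nb <- 0:n
  stat <- (nb - (n - nb))^2 / n
  p <- stats::pchisq(stat, 1, lower.tail = FALSE)
  sum(stats::dbinom(nb, n, 0.5)[p < alpha])
}

# small deterministic genotype matrix builder
toy_geno <- function(calls, segregants = NULL, markers = NULL) {
  m <- matrix(calls, nrow = length(calls) / length(markers), byrow = TRUE)
  rownames(m) <- segregants
  colnames(m) <- markers
  genotype_matrix(m)
}

# tiny marker panel on two chromosomes
toy_panel <- function() {
  marker_panel(chrom = c("I", "I", "I", "II", "II"),
               pos = c(10000L, 60000L, 200000L, 5000L, 400000L),
               allele_b = "A", allele_g = "C")
}
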