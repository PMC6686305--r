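# Independent brute-force oracles for the association indices and small
# combinatorial ensembles. Deliberately naive: plain loops and formulas,
# no shared code with the package internals.

oracle_checker <- function(m) {
  S <- nrow(m)
  count <- 0
  for (i in seq_len(S - 1)) for (j in (i + 1):S) {
    if (sum(m[i, ] * m[j, ]) == 0) count <- count + 1
  }
  count
}

oracle_cscore <- function(m) {
  S <- nrow(m)
  cu <- c()
  for (i in seq_len(S - 1)) for (j in (i + 1):S) {
    sh <- sum(m[i, ] * m[j, ])
    cu <- c(cu, (sum(m[i, ]) - sh) * (sum(m[j, ]) - sh))
  }
  mean(cu)
}

pop_var <- function(x) mean((x - mean(x))^2)

oracle_vratio <- function(m) {
  pop_var(colSums(m)) / sum(apply(m, 1, pop_var))
}

oracle_ca_aa <- function(m) {
  S <- nrow(m); T_ <- ncol(m)
  ca <- 0; aa <- 0
  for (i in seq_len(S - 1)) for (j in (i + 1):S) {
    for (k in seq_len(T_ - 1)) for (l in (k + 1):T_) {
      di <- m[i, k] - m[i, l]
      dj <- m[j, k] - m[j, l]
      if (di * dj < 0) ca <- ca + 1
      if (di * dj > 0) aa <- aa + 1
    }
  }
  n_sub <- choose(S, 2) * choose(T_, 2)
  c(ca / n_sub, aa / n_sub)
}

oracle_ma <- function(m) {
  p <- sweep(m, 2, colSums(m), "/")
  T_ <- ncol(m)
  num <- sum(rowSums(p)^2 - rowSums(p^2))
  num / ((T_ - 1) * sum(p^2))
}

# random 0/1 matrix guaranteed analyzable (>= 2 species, no all-zero rows)
random_binary <- function(S, T_, fill = 0.5) {
  repeat {
    m <- matrix(rbinom(S * T_, 1, fill), S, T_)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

random_counts <- function(S, T_, lambda = 2) {
  repeat {
    m <- matrix(rpois(S * T_, lambda), S, T_)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# exhaustive enumeration of all 0/1 matrices with the given marginals,
# bit-encoded to match cpp_sim9_codes (cell (i,k) -> bit i*T+k, 0-based)
enumerate_fixed_marginal <- function(rt, ct) {
  S <- length(rt); T_ <- length(ct)
  stopifnot(S * T_ <= 16)
  codes <- c()
  for (code in 0:(2^(S * T_) - 1)) {
    m <- matrix(bitwAnd(bitwShiftR(code, 0:(S * T_ - 1)), 1L),
                S, T_, byrow = TRUE)
    if (all(rowSums(m) == rt) && all(colSums(m) == ct)) {
      codes <- c(codes, code)
    }
  }
  codes
}

encode_binary <- function(m) {
  S <- nrow(m); T_ <- ncol(m)
  bits <- as.vector(t(m))  # row-major: bit i*T+k
  sum(bits * 2^(seq_along(bits) - 1))
}

# exact table distribution of the IT sequential fill, by recursive
# enumeration of every placement path (row drawn with prob proportional to
# observed row totals among unsaturated rows, column likewise)
oracle_it_distribution <- function(rt, ct) {
  S <- length(rt); T_ <- length(ct)
  probs <- new.env()
  recurse <- function(tab, prob) {
    placed_r <- rowSums(tab); placed_c <- colSums(tab)
    if (sum(tab) == sum(rt)) {
      key <- paste(tab, collapse = ",")
      probs[[key]] <- (probs[[key]] %||% 0) + prob
      return(invisible())
    }
    ar <- which(placed_r < rt); ac <- which(placed_c < ct)
    wr <- rt[ar] / sum(rt[ar]); wc <- ct[ac] / sum(ct[ac])
    for (ii in seq_along(ar)) for (kk in seq_along(ac)) {
      tab2 <- tab
      tab2[ar[ii], ac[kk]] <- tab2[ar[ii], ac[kk]] + 1
      recurse(tab2, prob * wr[ii] * wc[kk])
    }
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  recurse(matrix(0L, S, T_), 1)
  out <- sapply(ls(probs), function(k) probs[[k]])
  out / sum(out)
}

# quick outcome-record factory for tabulation tests
fake_records <- function(outcomes, ...) {
  tibble::tibble(
    dataset_id = paste0("d", seq_along(outcomes)),
    level = "assemblage", guild = NA_character_,
    model_type = "binary", algorithm = "SIM2", index = "C_SCORE",
    observed = 0, p_low = 1, p_high = 1, p_two = 1,
    outcome = outcomes, n_sim = 100, alpha = 0.05, ...
  )
}
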