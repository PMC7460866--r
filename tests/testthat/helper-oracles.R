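# Independent oracles kept deliberately separate from the implementation
# paths they check.

# brute-force binomial upper-tail by direct summation on the log scale
oracle_binom_tail <- function(alt, dp, p) {
  if (alt <= 0) return(1)
  if (alt > dp) return(0)
  k <- alt:dp
  sum(exp(lchoose(dp, k) + k * log(p) + (dp - k) * log1p(-p)))
}

# scalar character-by-character context classifier (loops, no string ops)
oracle_context <- function(s, up, dn) {
  sc <- strsplit(s, "")[[1]]
  uc <- strsplit(up, "")[[1]]
  dc <- strsplit(dn, "")[[1]]
  L <- length(sc)
  eq <- function(a, b) length(a) == length(b) && all(a == b)
  if (length(dc) >= L && eq(dc[1:L], sc)) {
    return(list(class = "rep", bimh = NA_integer_))
  }
  if (length(uc) >= L && eq(uc[(length(uc) - L + 1):length(uc)], sc)) {
    return(list(class = "rep", bimh = NA_integer_))
  }
  best <- 0L
  if (L >= 2) {
    for (m in 1:(L - 1)) {
      if (length(dc) >= m && eq(sc[1:m], dc[1:m])) best <- max(best, m)
      if (length(uc) >= m &&
            eq(sc[(L - m + 1):L], uc[(length(uc) - m + 1):length(uc)])) {
        best <- max(best, m)
      }
    }
  }
  if (best >= 1L) list(class = "mh", bimh = best)
  else list(class = "none", bimh = NA_integer_)
}

# vectorized character-matrix oracle over a set of equal-length reference
# strings, deleting ref[i..i+L-1]; scans columns of the character matrix
oracle_context_matrix <- function(M, i, L) {
  n <- nrow(M)
  w <- ncol(M)
  S <- M[, i:(i + L - 1), drop = FALSE]
  nU <- i - 1L
  nD <- w - (i + L - 1L)
  colmatch <- function(A, B) rowSums(A == B) == ncol(A)
  rep_dn <- if (nD >= L) {
    colmatch(M[, (i + L):(i + 2L * L - 1L), drop = FALSE], S)
  } else rep(FALSE, n)
  rep_up <- if (nU >= L) {
    colmatch(M[, (i - L):(i - 1L), drop = FALSE], S)
  } else rep(FALSE, n)
  is_rep <- rep_dn | rep_up
  best <- integer(n)
  if (L >= 2) {
    for (m in 1:(L - 1)) {
      pre <- if (nD >= m) {
        colmatch(M[, (i + L):(i + L + m - 1L), drop = FALSE],
                 S[, 1:m, drop = FALSE])
      } else rep(FALSE, n)
      suf <- if (nU >= m) {
        colmatch(M[, (i - m):(i - 1L), drop = FALSE],
                 S[, (L - m + 1L):L, drop = FALSE])
      } else rep(FALSE, n)
      best[pre | suf] <- m
    }
  }
  cls <- rep("none", n)
  cls[best >= 1L] <- "mh"
  cls[is_rep] <- "rep"
  bimh <- ifelse(!is_rep & best >= 1L, best, NA_integer_)
  list(class = cls, bimh = as.integer(bimh))
}
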