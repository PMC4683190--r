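# independent brute-force oracles shared by unit and acceptance tests

ci_bruteforce <- function(ranked, links) {
  w <- links$tau_corr / 2
  ref_ids <- links$ref_ids
  A <- links$A
  refev <- lapply(ref_ids, function(j) {
    if (j == 0L) ranked$rank[ranked$is_clock]
    else ranked$rank[!is.na(ranked$ref_unit) & ranked$ref_unit == j &
                     ranked$is_real]
  })
  out <- rep(NA_real_, nrow(ranked))
  for (e in seq_len(nrow(ranked))) {
    if (ranked$is_clock[e]) next
    u <- ranked$unit[e]
    if (is.na(u)) { out[e] <- 0; next }
    nj <- vapply(seq_along(ref_ids), function(jj) {
      cnt <- sum(abs(refev[[jj]] - ranked$rank[e]) <= w)
      if (!is.na(ranked$ref_unit[e]) && ranked$is_real[e] &&
          ranked$ref_unit[e] == ref_ids[jj]) cnt <- cnt - 1
      cnt
    }, numeric(1))
    tot <- sum(nj)
    if (tot == 0) { out[e] <- 0; next }
    arow <- A[as.character(u), ]
    linked <- which(arow == 1)
    if (length(linked) == 0) { out[e] <- 0; next }
    f1 <- sum(nj[linked]) / tot
    U <- linked[nj[linked] > 0]
    f2 <- 1
    if (length(U) >= 2) {
      np <- 0; nl <- 0
      for (a in seq_along(U)) for (b in seq_along(U)) if (a < b) {
        np <- np + 1
        ra <- match(as.character(ref_ids[U[a]]), rownames(A))
        rb <- match(as.character(ref_ids[U[b]]), rownames(A))
        fwd <- !is.na(ra) && A[ra, U[b]] == 1
        bwd <- !is.na(rb) && A[rb, U[a]] == 1
        if (fwd || bwd) nl <- nl + 1
      }
      f2 <- nl / np
    }
    out[e] <- f1 * f2
  }
  out
}

make_links <- function(units, ref_ids, linked_pairs, tau_corr = 100) {
  A <- matrix(0L, length(units), length(ref_ids),
              dimnames = list(units, ref_ids))
  for (p in linked_pairs) A[as.character(p[1]), as.character(p[2])] <- 1L
  structure(list(pairs = tibble::tibble(), A = A, tau_corr = tau_corr,
                 ref_ids = ref_ids), class = "mea_links")
}


brute_L <- function(ci, surr, P) {
  N <- length(ci)
  merged <- c(ci, surr)
  o <- order(merged)
  xs <- as.numeric(rep(c(FALSE, TRUE), c(N, length(surr)))[o])
  M <- length(xs)
  qpos <- which(!rep(c(FALSE, TRUE), c(N, length(surr)))[o])
  for (L in seq_len(M)) {
    f <- vapply(qpos, function(q) {
      idx <- (q - L):(q + L)
      idx <- abs(idx - 1) %% (2 * (M - 1))
      idx <- ifelse(idx >= M - 1, 2 * (M - 1) - idx, idx) + 1
      sum(xs[idx]) / (2 * L)
    }, numeric(1))
    if (sum(f) == 0) return(list(L = L, p = rep(0, N)))
    p <- f * P / sum(f)
    if (max(p) <= 1.1 || L == M)
      return(list(L = L, p_sorted = pmin(pmax(p, 0), 1)))
  }
}

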