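# Deliberately naive reference implementations, written as literal double
# loops over instances and catalog codes. They share no code with the package
# internals and serve as independent oracles for the equivalence tests.

oracle_medtric <- function(truth, pred, codes, s, w, C, floor_n = 1) {
  N <- length(truth)
  names(s) <- codes
  dimnames(w) <- list(codes, codes)
  dimnames(C) <- list(codes, codes)
  n <- sapply(codes, function(cj)
    sum(sapply(truth, function(y) cj %in% y)))

  t_of <- function(zlist) {
    total <- 0
    for (i in seq_len(N)) {
      y <- truth[[i]]
      z <- zlist[[i]]
      for (j in codes) {
        if (j %in% z && j %in% y) {
          a <- s[[j]] / n[[j]]
        } else if (j %in% y && !(j %in% z)) {
          a <- -s[[j]] / n[[j]]
        } else if (j %in% z && !(j %in% y)) {
          n_star <- max(n[y])
          a <- s[[j]] / n_star * (mean(sapply(y, function(k) w[j, k])) - 1)
        } else {
          a <- 0
        }
        b <- 0
        if (j %in% z) {
          acc <- 0
          for (k in z) acc <- acc + s[[k]] * C[j, k]
          nj <- if (n[[j]] == 0) floor_n else n[[j]]
          b <- -acc / nj
        }
        total <- total + a + b
      }
    }
    total
  }

  t_obs <- t_of(pred)
  t_null <- t_of(rep(list(character(0)), N))
  t_perf <- t_of(truth)
  list(score = (t_obs - t_null) / (t_perf - t_null),
       raw_t = t_obs, null_t = t_null, perfect_t = t_perf)
}

oracle_label_based <- function(truth, pred, codes) {
  div0 <- function(a, b) if (b == 0) 0 else a / b
  per <- t(sapply(codes, function(j) {
    tp <- fp <- fn <- 0
    for (i in seq_along(truth)) {
      in_y <- j %in% truth[[i]]
      in_z <- j %in% pred[[i]]
      if (in_y && in_z) tp <- tp + 1
      if (!in_y && in_z) fp <- fp + 1
      if (in_y && !in_z) fn <- fn + 1
    }
    c(tp = tp, fp = fp, fn = fn)
  }))
  p_j <- mapply(div0, per[, "tp"], per[, "tp"] + per[, "fp"])
  r_j <- mapply(div0, per[, "tp"], per[, "tp"] + per[, "fn"])
  f_j <- mapply(function(p, r) div0(2 * p * r, p + r), p_j, r_j)
  mp <- div0(sum(per[, "tp"]), sum(per[, "tp"]) + sum(per[, "fp"]))
  mr <- div0(sum(per[, "tp"]), sum(per[, "tp"]) + sum(per[, "fn"]))
  c(macro_precision = mean(p_j), macro_recall = mean(r_j),
    macro_f1 = mean(f_j), micro_precision = mp, micro_recall = mr,
    micro_f1 = div0(2 * mp * mr, mp + mr))
}

oracle_example_based <- function(truth, pred, P) {
  div0 <- function(a, b) if (b == 0) 0 else a / b
  N <- length(truth)
  acc <- c(hamming = 0, accuracy = 0, precision = 0, recall = 0, f1 = 0,
           subset_accuracy = 0)
  for (i in seq_len(N)) {
    y <- truth[[i]]
    z <- pred[[i]]
    inter <- length(intersect(y, z))
    sym <- length(setdiff(y, z)) + length(setdiff(z, y))
    acc <- acc + c(sym / P,
                   div0(inter, length(union(y, z))),
                   div0(inter, length(z)),
                   div0(inter, length(y)),
                   div0(2 * inter, length(y) + length(z)),
                   as.numeric(setequal(y, z)))
  }
  acc / N
}

oracle_challenge_metric <- function(truth, pred, codes, w, normal) {
  dimnames(w) <- list(codes, codes)
  t_of <- function(zlist) {
    tot <- 0
    for (i in seq_along(truth)) {
      y <- truth[[i]]
      z <- zlist[[i]]
      if (length(z) == 0) next
      u <- length(union(y, z))
      for (j in y) for (k in z) tot <- tot + w[j, k] / u
    }
    tot
  }
  t_obs <- t_of(pred)
  t_perf <- t_of(truth)
  t_nsr <- t_of(rep(list(normal), length(truth)))
  (t_obs - t_nsr) / (t_perf - t_nsr)
}

# brute-force classification of a (truth, prediction) pair by definition
oracle_classify <- function(y, z) {
  if (setequal(y, z)) "perfect"
  else if (all(z %in% y)) "missed"            # proper subset (incl. empty)
  else if (all(y %in% z)) "over"
  else if (length(intersect(y, z)) == 0 && length(z) > 0) "wrong"
  else "mixed"
}
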