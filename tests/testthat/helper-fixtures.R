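# Shared fixtures, all built in code.

# Table-5-style contingency: two ground-truth patterns, the first detected
# perfectly `n1_perfect` times and with its rarer code dropped `n1_missed`
# times, the second always perfect.
contingency_set <- function(n1_perfect, n1_missed, n2_perfect) {
  cat3 <- diagnosis_catalog(c("X", "A", "B"))
  truth <- c(rep(list(c("X", "A")), n1_perfect + n1_missed),
             rep(list(c("A", "B")), n2_perfect))
  pred <- c(rep(list(c("X", "A")), n1_perfect),
            rep(list("A"), n1_missed),
            rep(list(c("A", "B")), n2_perfect))
  evaluation_set(truth, pred, cat3)
}

table5_case1 <- function() contingency_set(50, 50, 900)
table5_case2 <- function() contingency_set(450, 450, 100)

ecg_catalog <- function()
  diagnosis_catalog(c("CRBBB", "AF", "QAb", "LAD", "STach", "NSIVCB"))

singleton_set <- function(truth, pred, catalog = ecg_catalog())
  evaluation_set(list(truth), list(pred), catalog)

# builds a set where every class has n_per single-label instances, fn[k] of
# them missed and fp[k] extra predictions of code k planted on other classes;
# uniform prevalence, so every class sits at n_k = n*
margin_set <- function(catalog, n_per, fn, fp) {
  codes <- catalog$codes
  P <- length(codes)
  truth <- pred <- list()
  for (j in seq_len(P)) {
    for (i in seq_len(n_per)) {
      truth <- c(truth, list(codes[j]))
      pred <- c(pred, list(if (i <= fn[j]) character(0) else codes[j]))
    }
  }
  for (j in seq_len(P)) {
    hosts <- which(vapply(truth, function(y) y != codes[j], logical(1)))
    for (h in hosts[seq_len(fp[j])])
      pred[[h]] <- c(pred[[h]], codes[j])
  }
  evaluation_set(truth, pred, catalog)
}

# random evaluation set + config for oracle-equivalence and property tests;
# uses the current RNG state
rand_case <- function(P_max = 5, N_max = 20, with_contra = FALSE) {
  P <- sample(2:P_max, 1)
  N <- sample(1:N_max, 1)
  codes <- LETTERS[seq_len(P)]
  catalog <- diagnosis_catalog(codes)
  w <- matrix(runif(P * P, 0.05, 0.95), P, P)
  w <- (w + t(w)) / 2
  diag(w) <- 1
  C <- NULL
  if (with_contra && P >= 3) {
    C <- matrix(0, P, P, dimnames = list(codes, codes))
    C[1, 2] <- C[2, 1] <- 1
  }
  config <- metric_config(catalog,
                          significance = runif(P, 0.2, 3),
                          similarity = w,
                          contradiction = C)
  truth <- lapply(seq_len(N), function(i) {
    k <- sample(P, 1)
    y <- sample(codes, k)
    if (!is.null(C)) y <- setdiff(y, if ("A" %in% y) "B" else character(0))
    if (length(y) == 0) y <- "A"
    y
  })
  pred <- lapply(seq_len(N), function(i)
    sample(codes, sample(0:P, 1)))
  es <- evaluation_set(truth, pred, catalog, config = config)
  list(es = es, config = config, codes = codes)
}
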