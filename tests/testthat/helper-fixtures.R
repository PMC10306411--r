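# Shared fixtures: tiny hand-checkable objects and the seeded random
# projection instances used by both the unit and acceptance suites.

tiny_dataset <- function(cols, q = seq_len(nrow(cols)), t = NULL) {
  cols <- base::as.matrix(cols)
  if (is.null(t)) t <- seq_len(ncol(cols))
  trxl_dataset(q = q, t = t, matrix = cols)
}

curve_on <- function(q, values, label = "c") trxl_curve(q, values, label)

# Random dataset + trivial set, including rank-deficient trivial sets
# (duplicated / linearly combined components).
random_projection_instance <- function(seed) {
  set.seed(seed)
  n_q <- sample(3:50, 1)
  n_t <- sample(2:8, 1)
  m <- sample(1:5, 1)
  q <- sort(runif(n_q, 0.1, 10))
  while (any(diff(q) < 1e-6)) q <- sort(runif(n_q, 0.1, 10))
  ds <- trxl_dataset(q, seq_len(n_t),
                     matrix(rnorm(n_q * n_t), n_q, n_t))
  comps <- lapply(seq_len(m), function(i)
    trxl_curve(q, rnorm(n_q), paste0("t", i)))
  # half the instances get a rank-deficient set: replace one component by a
  # linear combination of the others (or a scaled duplicate when m == 1)
  if (m >= 1 && seed %% 2 == 0) {
    if (m == 1) {
      comps[[2]] <- trxl_curve(q, 2.5 * comps[[1]]$values, "dup")
    } else {
      w <- rnorm(m - 1)
      comb <- Reduce(`+`, Map(function(cv, wi) wi * cv$values,
                              comps[-m], as.list(w)))
      comps[[m]] <- trxl_curve(q, comb, "comb")
    }
  }
  list(ds = ds, trivials = trivial_set(comps))
}

rel_l2 <- function(x, y) {
  sqrt(sum((x - y)^2)) / max(sqrt(sum(y^2)), .Machine$double.xmin)
}

# largest principal angle (radians) between the column spans of A and B
subspace_angle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(min(1, max(-1, min(s))))
}
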