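test_that("dynamic margins respect their bounds and decay with class size", {
  mt <- compute_margins(1L)
  expect_equal(mt$margins, 0.5)

  big <- compute_margins(10^12)
  expect_equal(big$margins, 0.05, tolerance = 1e-5)

  n1000 <- compute_margins(1000L)
  expect_equal(n1000$margins, 0.45 / sqrt(1000) + 0.05, tolerance = 1e-12)

  counts <- c(3L, 3L, 10L, 100L, 5000L)
  m <- compute_margins(counts)$margins
  expect_true(all(diff(m[order(counts)]) <= 0))
  expect_true(all(m >= 0.05 & m <= 0.5))

  expect_error(compute_margins(c(5L, 0L)), "must be >= 1")
  expect_error(compute_margins(5L, a = 0.1, b = 0.2), "b < a")
})

test_that("class cosines take the best sub-center and ignore embedding scale", {
  # K = 1, aligned unit vectors
  W1 <- matrix(c(1, 0, 0), 1, 3)
  r <- subcenter_cosines(c(1, 0, 0), W1, K = 1L)
  expect_equal(r$cosines, 1 - 1e-7)

  # K = 3, one class with sub-centers at cosines (0.2, 0.9, -0.5) to e1
  mk <- function(c1) c(c1, sqrt(1 - c1^2), 0)
  W3 <- rbind(mk(0.2), mk(0.9), mk(-0.5))
  r3 <- subcenter_cosines(c(1, 0, 0), W3, K = 3L)
  expect_equal(r3$cosines, 0.9, tolerance = 1e-12)
  expect_equal(r3$which_k, 2L)

  # brute-force oracle over all N*K dot products
  set.seed(21)
  W <- matrix(rnorm(4 * 3 * 5), 12, 5)
  x <- rnorm(5)
  got <- subcenter_cosines(x, W, K = 3L)
  xn <- x / sqrt(sum(x^2))
  brute <- sapply(1:4, function(j) {
    max(sapply(1:3, function(k) {
      w <- W[(j - 1) * 3 + k, ]
      sum(w / sqrt(sum(w^2)) * xn)
    }))
  })
  expect_equal(got$cosines, pmin(pmax(brute, -1 + 1e-7), 1 - 1e-7), tolerance = 1e-12)

  expect_equal(subcenter_cosines(3.7 * x, W, K = 3L)$cosines, got$cosines)
  expect_error(subcenter_cosines(rep(0, 5), W, K = 3L), "non-zero")
})

test_that("margin logits apply the angular margin stably to the target only", {
  cosines <- c(0.3, -0.2, 0.8)
  expect_equal(margin_logits(cosines, 2L, m = 0, s = 64), 64 * cosines)

  z <- margin_logits(c(1, 0), 1L, m = 0.5, s = 64)
  expect_equal(z[1], 64 * cos(0.5), tolerance = 1e-12)

  # the margin strictly lowers the target logit on (0, pi - m)
  withr::with_seed(22, {
    for (i in 1:25) {
      theta <- runif(1, 0.01, pi - 0.51)
      z0 <- margin_logits(c(cos(theta), 0), 1L, m = 0, s = 64)
      z1 <- margin_logits(c(cos(theta), 0), 1L, m = 0.5, s = 64)
      expect_lt(z1[1], z0[1])
    }
  })
})

test_that("the loss reduces to softmax cross-entropy without margins", {
  # closed-form two-class case: cosines (1, 0), m = 0, s = 1
  W <- rbind(c(1, 0), c(0, 1))
  mt <- structure(list(margins = c(0, 0)), class = "margin_table")
  r <- dsa_loss(matrix(c(1, 0), 1), 1L, W, mt, loss_config(s = 1), K = 1L)
  expect_equal(r$loss, -log(exp(1) / (exp(1) + 1)), tolerance = 1e-4)

  # random batches: m = 0, K = 1 equals CE over s-scaled cosine logits
  set.seed(23)
  for (rep in 1:5) {
    D <- 6; C <- 4; B <- 8
    W <- matrix(rnorm(C * D), C, D)
    X <- matrix(rnorm(B * D), B, D)
    y <- sample(C, B, replace = TRUE)
    mt0 <- structure(list(margins = rep(0, C)), class = "margin_table")
    got <- dsa_loss(X, y, W, mt0, loss_config(s = 64), K = 1L)$loss
    Wn <- W / sqrt(rowSums(W^2))
    ce <- mean(sapply(1:B, function(i) {
      cn <- as.vector(Wn %*% (X[i, ] / sqrt(sum(X[i, ]^2))))
      z <- 64 * pmin(pmax(cn, -1 + 1e-7), 1 - 1e-7)
      -(z[y[i]] - log(sum(exp(z - max(z)))) - max(z))
    }))
    expect_equal(got, ce, tolerance = 1e-10)
  }
})

test_that("adding a margin never decreases the loss", {
  set.seed(24)
  for (rep in 1:10) {
    D <- 5; C <- 3; B <- 6; K <- 2
    W <- matrix(rnorm(C * K * D), C * K, D)
    X <- matrix(rnorm(B * D), B, D)
    y <- sample(C, B, replace = TRUE)
    mt0 <- structure(list(margins = rep(0, C)), class = "margin_table")
    mt1 <- compute_margins(sample(1:50, C))
    l0 <- dsa_loss(X, y, W, mt0, loss_config(), K = K)$loss
    l1 <- dsa_loss(X, y, W, mt1, loss_config(), K = K)$loss
    expect_gte(l1, l0)
  }
})

test_that("the loss matches a naive direct transcription of its formula", {
  naive_loss <- function(X, y, W, margins, s, K) {
    C <- nrow(W) / K
    mean(sapply(seq_len(nrow(X)), function(i) {
      x <- X[i, ]; xn <- x / sqrt(sum(x^2))
      theta <- sapply(1:C, function(j) {
        dots <- sapply(1:K, function(k) {
          w <- W[(j - 1) * K + k, ]
          sum(w / sqrt(sum(w^2)) * xn)
        })
        acos(pmin(pmax(max(dots), -1 + 1e-7), 1 - 1e-7))
      })
      yy <- y[i]
      num <- exp(s * cos(theta[yy] + margins[yy]))
      den <- num + sum(exp(s * cos(theta[-yy])))
      -log(num / den)
    }))
  }
  set.seed(25)
  for (rep in 1:100) {
    D <- sample(2:8, 1); C <- sample(2:5, 1); K <- sample(1:3, 1)
    B <- sample(1:16, 1)
    W <- matrix(rnorm(C * K * D), C * K, D)
    X <- matrix(rnorm(B * D), B, D)
    y <- sample(C, B, replace = TRUE)
    mt <- compute_margins(sample(1:2000, C))
    got <- dsa_loss(X, y, W, mt, loss_config(s = 10), K = K)$loss
    want <- naive_loss(X, y, W, mt$margins, s = 10, K = K)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("analytic loss gradients match finite differences", {
  set.seed(26)
  D <- 6; C <- 3; K <- 2; B <- 4
  W <- matrix(rnorm(C * K * D), C * K, D)
  X <- matrix(rnorm(B * D), B, D)
  y <- sample(C, B, replace = TRUE)
  mt <- compute_margins(c(4L, 40L, 400L))
  lc <- loss_config(s = 8)
  r <- dsa_loss(X, y, W, mt, lc, K = K, grads = TRUE)
  eps <- 1e-6
  f <- function(Xp, Wp) dsa_loss(Xp, y, Wp, mt, lc, K = K)$loss
  for (trial in 1:10) {
    i <- sample(B, 1); j <- sample(D, 1)
    Xp <- X; Xm <- X
    Xp[i, j] <- Xp[i, j] + eps; Xm[i, j] <- Xm[i, j] - eps
    expect_equal(r$dembeddings[i, j], (f(Xp, W) - f(Xm, W)) / (2 * eps),
                 tolerance = 1e-4)
    a <- sample(nrow(W), 1); b <- sample(D, 1)
    Wp <- W; Wm <- W
    Wp[a, b] <- Wp[a, b] + eps; Wm[a, b] <- Wm[a, b] - eps
    expect_equal(r$dW[a, b], (f(X, Wp) - f(X, Wm)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("labels outside the class range are rejected", {
  W <- matrix(rnorm(6), 2, 3)
  mt <- compute_margins(c(5L, 5L))
  expect_error(dsa_loss(matrix(1:3, 1), 3L, W, mt, K = 1L), "out of range")
})
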