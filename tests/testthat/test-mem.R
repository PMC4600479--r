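# small random MEM problem shared by several blocks
mem_toy <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    geo <- tiny_cortex(1)
    set.seed(42)
    p <- nrow(geo$mesh$vertices)
    q <- 12
    G <- matrix(rnorm(q * p), q, p) / sqrt(q)
    scores <- runif(p)
    parc <- ddp_parcellate(scores, geo$mesh, scale = 2)
    alpha <- init_alpha(parc, scores)
    model <- build_reference_model(parc, alpha, geo$mesh, eta = 0.5)
    cache <<- list(geo = geo, G = G, parc = parc, alpha = alpha,
                   model = model, sigma_d = runif(q, 0.5, 1.5),
                   m = rnorm(q), q = q, p = p)
    cache
  }
})

test_that("reference model covariances are symmetric positive definite", {
  geo <- tiny_cortex(1)
  set.seed(1)
  for (r in 1:10) {
    scores <- runif(nrow(geo$mesh$vertices))
    parc <- ddp_parcellate(scores, geo$mesh, scale = sample(1:3, 1))
    model <- build_reference_model(parc, init_alpha(parc, scores),
                                   geo$mesh, eta = runif(1, 0.1, 2))
    for (k in sample(parc$K, min(5, parc$K))) {
      S <- memfusion:::sigma_dense(model, k)
      expect_equal(S, t(S), tolerance = 1e-12)
      expect_gt(min(eigen(S, symmetric = TRUE,
                          only.values = TRUE)$values), 0)
    }
  }
  # singleton parcel and smoothing order 0 edge cases
  m1 <- scalar_model(0.5, 2)
  expect_equal(memfusion:::sigma_dense(m1, 1)[1, 1], 2 * (1 + 1e-4))
  expect_error(build_reference_model(mem_toy()$parc, mem_toy()$alpha,
                                     tiny_cortex(1)$mesh, eta = 0),
               "eta")
})

test_that("dual objective at zero is 0 with gradient equal to the data", {
  toy <- mem_toy()
  d0 <- mem_dual_objective(numeric(toy$q), toy$model, toy$m, toy$G,
                           toy$sigma_d)
  expect_equal(d0$value, 0)
  expect_equal(d0$gradient, toy$m)
})

test_that("analytic gradient matches finite differences", {
  toy <- mem_toy()
  set.seed(2)
  l0 <- rnorm(toy$q, sd = 0.3)
  d <- mem_dual_objective(l0, toy$model, toy$m, toy$G, toy$sigma_d)
  eps <- 1e-6
  for (i in sample(toy$q, 6)) {
    e <- numeric(toy$q); e[i] <- eps
    fd <- (mem_dual_objective(l0 + e, toy$model, toy$m, toy$G,
                              toy$sigma_d)$value -
           mem_dual_objective(l0 - e, toy$model, toy$m, toy$G,
                              toy$sigma_d)$value) / (2 * eps)
    expect_equal(d$gradient[i], fd, tolerance = 1e-6)
  }
  expect_error(mem_dual_objective(rep(NaN, toy$q), toy$model, toy$m,
                                  toy$G, toy$sigma_d), "finite")
})

test_that("the dual is concave along random line segments", {
  toy <- mem_toy()
  set.seed(3)
  for (r in 1:20) {
    a <- rnorm(toy$q, sd = 0.5)
    b <- rnorm(toy$q, sd = 0.5)
    vals <- vapply(seq(-1, 1, length.out = 9), function(tt) {
      mem_dual_objective(a + tt * b, toy$model, toy$m, toy$G,
                         toy$sigma_d)$value
    }, numeric(1))
    expect_true(all(diff(diff(vals)) <= 1e-8 * max(1, abs(vals))))
  }
})

test_that("numeric Hessian of the negated dual is positive semidefinite", {
  toy <- mem_toy()
  set.seed(4)
  q <- toy$q
  for (r in 1:5) {
    l0 <- rnorm(q, sd = 0.4)
    H <- matrix(0, q, q)
    eps <- 1e-5
    for (i in seq_len(q)) {
      e <- numeric(q); e[i] <- eps
      gp <- mem_dual_objective(l0 + e, toy$model, toy$m, toy$G,
                               toy$sigma_d)$gradient
      gm <- mem_dual_objective(l0 - e, toy$model, toy$m, toy$G,
                               toy$sigma_d)$gradient
      H[, i] <- -(gp - gm) / (2 * eps)
    }
    H <- (H + t(H)) / 2
    expect_gt(min(eigen(H, symmetric = TRUE, only.values = TRUE)$values),
              -1e-6)
  }
})

test_that("alpha -> 1 recovers the Gaussian-prior dual and estimate", {
  toy <- mem_toy()
  model1 <- build_reference_model(toy$parc, rep(1 - 1e-10, toy$parc$K),
                                  toy$geo$mesh, eta = 0.5)
  # dual value equals the explicit Gaussian expression
  set.seed(5)
  l0 <- rnorm(toy$q, sd = 0.3)
  d <- mem_dual_objective(l0, model1, toy$m, toy$G, toy$sigma_d)
  quad <- 0
  for (k in seq_len(model1$K)) {
    idx <- model1$parcels[[k]]
    xk <- crossprod(toy$G[, idx, drop = FALSE], l0)[, 1]
    quad <- quad + 0.5 * sum(xk * (memfusion:::sigma_dense(model1, k) %*%
                                     xk))
  }
  gauss <- sum(l0 * toy$m) - 0.5 * sum(toy$sigma_d * l0^2) - quad
  expect_equal(d$value, gauss, tolerance = 1e-7)
  # solution matches the closed-form Gaussian estimate
  fit <- solve_mem_timepoint(toy$m, toy$G, model1, toy$sigma_d)
  Sig_s <- matrix(0, toy$p, toy$p)
  for (k in seq_len(model1$K)) {
    idx <- model1$parcels[[k]]
    Sig_s[idx, idx] <- memfusion:::sigma_dense(model1, k)
  }
  J_cf <- Sig_s %*% t(toy$G) %*%
    solve(toy$G %*% Sig_s %*% t(toy$G) + diag(toy$sigma_d), toy$m)
  expect_lt(memfusion:::vec_norm(fit$J - J_cf) /
              memfusion:::vec_norm(J_cf), 1e-6)
})

test_that("zero data yields the zero solution", {
  toy <- mem_toy()
  fit <- solve_mem_timepoint(numeric(toy$q), toy$G, toy$model,
                             toy$sigma_d)
  expect_equal(fit$J, numeric(toy$p))
  expect_equal(fit$state$lambda, numeric(toy$q))
})

test_that("scalar toy optimum matches a dense grid search", {
  model <- scalar_model(alpha = 0.6, eta = 1.3)
  G1 <- matrix(2, 1, 1)
  fit <- solve_mem_timepoint(0.8, G1, model, 0.4)
  grid <- seq(-5, 5, by = 1e-4)
  vals <- vapply(grid, function(l) {
    mem_dual_objective(l, model, 0.8, G1, 0.4)$value
  }, numeric(1))
  expect_equal(fit$state$lambda, grid[which.max(vals)],
               tolerance = 1e-3)
})

test_that("primal feasibility holds at the dual optimum", {
  toy <- mem_toy()
  fit <- solve_mem_timepoint(toy$m, toy$G, toy$model, toy$sigma_d)
  feas <- memfusion:::vec_norm(toy$m - toy$G %*% fit$J -
                                 toy$sigma_d * fit$state$lambda)
  expect_lt(feas, 1e-6 * memfusion:::vec_norm(toy$m))
  expect_true(fit$state$converged)
})

test_that("parcels shut down continuously as alpha -> 0", {
  toy <- mem_toy()
  k_target <- 1L
  idx <- toy$model$parcels[[k_target]]
  norms <- vapply(c(0.3, 0.1, 0.01, 1e-3, 1e-5), function(a) {
    alpha <- toy$alpha
    alpha[k_target] <- a
    model <- build_reference_model(toy$parc, alpha, toy$geo$mesh,
                                   eta = 0.5)
    fit <- solve_mem_timepoint(toy$m, toy$G, model, toy$sigma_d)
    memfusion:::vec_norm(fit$J[idx])
  }, numeric(1))
  expect_true(all(diff(norms) < 1e-8))
  expect_lt(norms[5], 1e-3 * norms[1])
})

test_that("solve_mem applies the per-sample solver columnwise", {
  toy <- mem_toy()
  M <- cbind(toy$m, 0.3 * toy$m, -toy$m)
  est <- solve_mem(M, toy$G, toy$model, toy$sigma_d,
                   opts = list(fix_eta = TRUE))
  one <- solve_mem_timepoint(toy$m, toy$G, toy$model, toy$sigma_d)
  expect_equal(est$J[, 1], one$J, tolerance = 1e-6)
  # per-sample independence: reversing time reverses the output
  est_rev <- solve_mem(M[, 3:1], toy$G, toy$model, toy$sigma_d,
                       opts = list(fix_eta = TRUE))
  expect_equal(est_rev$J, est$J[, 3:1], tolerance = 1e-8)
  expect_s3_class(est$diagnostics, "tbl_df")
  expect_equal(nrow(est$diagnostics), 3)
})

test_that("noiseless single-patch data localizes to the patch", {
  geo <- tiny_cortex(2)
  mesh <- geo$mesh
  lf <- meg_leadfield_sphere(mesh, geo$head, geo$meg)
  seedv <- which.max(mesh$vertices[, 3])
  patch <- grow_patch(mesh, seedv, 1)
  sim <- simulate_static(mesh, list(MEG = lf), patch,
                         noise = list(target_ratio = Inf), seed = 9)
  pk <- sim$spikes[[1]]$peak_index
  M <- sim$M$MEG[, pk, drop = FALSE] * 1e12      # avoid denormal scales
  G <- lf$G * 1e12
  msp <- msp_scores(M, G, l = 1)
  parc <- ddp_parcellate(msp, mesh, scale = 2)
  model <- build_reference_model(parc, init_alpha(parc, msp), mesh)
  est <- solve_mem(M, G, model, sigma_d = rep(1e-6 * max(abs(M))^2,
                                              nrow(G)))
  auc <- roc_auc(abs(est$J[, 1]), patch, mesh, seed = 1)
  expect_gt(auc, 0.9)
})
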