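test_that("parent selection keeps the top fraction with stable ties", {
  expect_identical(select_parents(c(2, 1, 3), 1), 1:3)
  expect_identical(select_parents(c(5, 1, 4, 2, 3), 0.4), c(1L, 3L))
  # tie at the cutoff: lower index wins
  expect_identical(select_parents(c(3, 3, 1), 0.34), 1L)
  # half-up rounding of F * n, floor at one parent
  expect_length(select_parents(rep(1, 10), 0.25), 3)
  expect_length(select_parents(rep(1, 10), 0.04), 1)
  expect_error(select_parents(numeric(0), 0.5), "at least one")
  expect_error(select_parents(1:5, 0), "parent_fraction")
})

test_that("center update rules follow their formulas", {
  expect_equal(hill_climb_center(matrix(c(3, 7), 1)), c(3, 7))
  expect_equal(hill_climb_center(rbind(c(0, 0), c(2, 2))), c(1, 1))
  sym <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)) + 5
  expect_equal(hill_climb_center(sym), c(5, 5))
  expect_equal(projection_center(c(0, 0), matrix(c(1, 1), 1)), c(2, 2))
  expect_equal(projection_center(c(4, 4), rbind(c(3, 3), c(5, 5))), c(4, 4))
  expect_equal(projection_center(c(100, 100), matrix(c(150, 100), 1)),
               c(200, 100))
})

test_that("cma update weights parents by fitness and adapts the shape", {
  parents <- rbind(c(1, 0), c(3, 0), c(2, 4))
  # equal fitnesses: plain mean
  upd <- cma_update(c(0, 0), parents, c(2, 2, 2), diag(2), radius = 1)
  expect_equal(upd$center, colMeans(parents))
  # spread only along axis 1: adapted shape is wider along axis 1
  ax1 <- cbind(seq(-3, 3), rep(0, 7))
  upd1 <- cma_update(c(0, 0), ax1, rep(1, 7), diag(2), radius = 1)
  expect_gt(upd1$shape[1, 1], upd1$shape[2, 2])
  # zero mean-shift with c_1 = 0 reduces to the blend formula
  symp <- rbind(c(1, 0), c(-1, 0), c(0, 2), c(0, -2))
  upd2 <- cma_update(c(0, 0), symp, rep(3, 4), diag(2), radius = 1,
                     c_mu = 0.5, c_1 = 0)
  wcov <- crossprod(symp * sqrt(0.25))
  expect_equal(upd2$shape, 0.5 * diag(2) + 0.5 * wcov)
  # fitness-proportional weights after min-shift
  upd3 <- cma_update(c(0, 0), rbind(c(0, 0), c(10, 0)), c(1, 3), diag(2),
                     radius = 1)
  expect_equal(upd3$center, c(10, 0)) # all weight on the fitter parent
  expect_error(cma_update(c(0, 0), matrix(c(1, 1), 1), 1, diag(2)),
               "2 parents")
})

test_that("cma shape matrix stays symmetric positive-definite under iteration", {
  set.seed(42)
  shape <- diag(2)
  center <- c(0, 0)
  for (i in 1:100) {
    parents <- matrix(rnorm(10, sd = 2), ncol = 2)
    fits <- runif(5)
    upd <- suppressWarnings(
      cma_update(center, parents, fits, shape, radius = 2))
    shape <- upd$shape
    center <- upd$center
    expect_equal(shape, t(shape))
    expect_true(all(eigen(shape, symmetric = TRUE,
                          only.values = TRUE)$values > 0))
  }
})

test_that("optimization traces have the promised structure and determinism", {
  ls1 <- single_peak(amplitude = 10, spread = c(150, 150))
  cfg <- optimizer_config("hill_climb", start = c(200, 200),
                          sobol_radius = 150, samples_per_iteration = 30,
                          iterations = 1, parent_fraction = 0.2, seed = 3)
  tr1 <- run_optimization(cfg, ls1)
  expect_length(tr1$iterations, 1)
  expect_equal(tr1$iterations[[1]]$center, c(200, 200))
  expect_equal(tr1$iterations[[1]]$center_fitness, evaluate(ls1, c(200, 200)))

  for (alg in c("hill_climb", "projection", "cma_es")) {
    cfg5 <- optimizer_config(alg, start = c(200, 200), sobol_radius = 150,
                             samples_per_iteration = 30, iterations = 5,
                             parent_fraction = 0.2, seed = 11)
    ta <- run_optimization(cfg5, ls1)
    tb <- run_optimization(cfg5, ls1)
    expect_identical(ta, tb) # bitwise reproducible from (config, seed)
    expect_length(ta$iterations, 5)
    for (rec in ta$iterations) {
      # parents are among the samples and dominate every non-parent
      expect_true(all(rec$parent_indices %in% seq_len(30)))
      pf <- rec$sample_fitnesses[rec$parent_indices]
      npf <- rec$sample_fitnesses[-rec$parent_indices]
      expect_gte(min(pf), max(npf))
    }
  }
  expect_error(optimizer_config("simplex", start = c(0, 0), sobol_radius = 1,
                                samples_per_iteration = 5,
                                parent_fraction = 0.5),
               "should be one of")
})

test_that("hill-climb centers stay in the parents' convex hull; projection can leave it", {
  # parents on a segment: hill-climb center is inside, the twofold
  # projection from a previous center off the segment is not
  parents <- rbind(c(10, 10), c(20, 10))
  hc <- hill_climb_center(parents)
  expect_true(hc[1] >= 10 && hc[1] <= 20 && hc[2] == 10)
  pj <- projection_center(c(0, 0), parents)
  expect_equal(pj, c(30, 20))
  inhull <- pj[1] >= 10 && pj[1] <= 20 && pj[2] == 10
  expect_false(inhull)
})

test_that("with F = 1 the expected hill-climb step climbs a linear ramp", {
  # fitness increases along +x; the selection-free (F = 1) cloud mean
  # displacement should track the gradient on average over seeds
  ramp <- function(pts) pts[, 1]
  disp <- vapply(1:40, function(s) {
    eng <- sobol_engine(2, seed = s)
    cl <- sample_cloud(eng, c(0, 0), radius = 50, n = 64, bounds = NULL)
    mean(cl$points[, 1])
  }, numeric(1))
  expect_lt(abs(mean(disp)), 10) # F = 1: symmetric cloud, no drift
  # with selection (F = 0.25) the parent mean moves up the gradient
  drift <- vapply(1:40, function(s) {
    eng <- sobol_engine(2, seed = s)
    cl <- sample_cloud(eng, c(0, 0), radius = 50, n = 64, bounds = NULL)
    idx <- select_parents(ramp(cl$points), 0.25)
    hill_climb_center(cl$points[idx, , drop = FALSE])[1]
  }, numeric(1))
  expect_gt(mean(drift), 25)
})

test_that("trace export lists centers, samples and parents per iteration", {
  ls1 <- single_peak()
  cfg <- optimizer_config("projection", start = c(300, 300),
                          sobol_radius = 100, samples_per_iteration = 10,
                          iterations = 3, parent_fraction = 0.3, seed = 2)
  tr <- run_optimization(cfg, ls1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace_tsv(tr, path)
  tab <- read.delim(path)
  expect_equal(sum(tab$role == "center"), 3)
  expect_equal(sum(tab$role == "sample"), 30)
  expect_equal(sum(tab$role == "parent"), 9)
})
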