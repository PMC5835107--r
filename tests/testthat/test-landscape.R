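test_that("landscape constructor validates its invariants", {
  expect_s3_class(single_peak(), "sobol_landscape")
  expect_error(single_peak(spread = c(0, 100)), "spread")
  expect_error(single_peak(amplitude = -1), "amplitudes")
  expect_error(single_peak(center = c(2000, 500)), "within bounds")
  expect_error(
    landscape(centers = matrix(numeric(0), 0, 2), amplitudes = numeric(0),
              spreads = matrix(numeric(0), 0, 2)),
    "at least one peak")
})

test_that("evaluate returns the Gaussian-sum value", {
  ls1 <- single_peak(amplitude = 3)
  expect_identical(evaluate(ls1, c(500, 500)), 3)
  # co-centered peaks add
  ls2 <- landscape(centers = rbind(c(500, 500), c(500, 500)),
                   amplitudes = c(1, 2),
                   spreads = rbind(c(100, 100), c(50, 50)))
  expect_identical(evaluate(ls2, c(500, 500)), 3)
  # Gaussian decay: 10 spreads out the value is negligible
  expect_lt(evaluate(single_peak(), c(500 + 10 * 100, 500)), 1e-20)
  expect_error(evaluate(ls1, c(1, 2, 3)), "dimensions")
})

test_that("evaluate_batch matches evaluate pointwise", {
  ls1 <- landscape(centers = rbind(c(200, 300), c(700, 600)),
                   amplitudes = c(2, 5),
                   spreads = rbind(c(120, 90), c(60, 200)))
  expect_identical(evaluate_batch(ls1, matrix(numeric(0), 0, 2)), numeric(0))
  cc <- matrix(rep(c(200, 300), 2), ncol = 2, byrow = TRUE)
  expect_equal(evaluate_batch(ls1, cc)[1], evaluate_batch(ls1, cc)[2])
  set.seed(11)
  pts <- matrix(runif(200, -100, 1100), ncol = 2)
  expect_identical(evaluate_batch(ls1, pts),
                   apply(pts, 1, function(p) evaluate(ls1, p)))
})

test_that("fitness is invariant under peak permutation and joint translation", {
  set.seed(3)
  centers <- matrix(runif(10, 100, 900), ncol = 2)
  amps <- runif(5, 1, 5)
  spreads <- matrix(runif(10, 40, 200), ncol = 2)
  ls_a <- landscape(centers, amps, spreads)
  perm <- c(3, 1, 5, 2, 4)
  ls_b <- landscape(centers[perm, ], amps[perm], spreads[perm, ])
  p <- c(432.5, 615.2)
  expect_equal(evaluate(ls_a, p), evaluate(ls_b, p))
  # translate everything by the same vector
  shift <- c(55.5, -123.25)
  ls_c <- landscape(sweep(centers, 2, shift, "+"), amps, spreads,
                    bounds = rbind(c(-500, -500), c(1500, 1500)))
  expect_equal(evaluate(ls_c, p + shift), evaluate(ls_a, p))
})

test_that("grid_sample covers the bounds with the requested resolution", {
  ls1 <- landscape(centers = matrix(c(5, 5), 1), amplitudes = 1,
                   spreads = matrix(c(3, 3), 1),
                   bounds = rbind(c(0, 0), c(10, 10)))
  g <- grid_sample(ls1, 3)
  expect_equal(nrow(g$points), 9)
  expect_setequal(unique(as.vector(g$points)), c(0, 5, 10))
  expect_identical(g$fitnesses, evaluate_batch(ls1, g$points))
  expect_error(grid_sample(ls1, 1), "points_per_axis")
  # the default quantification grid is 200 x 200 = 40,000 points
  g200 <- grid_sample(single_peak(), 200)
  expect_equal(nrow(g200$points), 40000)
  expect_equal(range(g200$points[, 1]), c(0, 1000))
})

test_that("landscape specs round-trip through JSON save/load", {
  ls1 <- landscape(centers = rbind(c(500.125, 500.375), c(100.1, 900.9)),
                   amplitudes = c(1.2345678901234567, 2),
                   spreads = rbind(c(100.5, 99.5), c(33.25, 44.75)),
                   name = "roundtrip")
  path <- withr::local_tempfile(fileext = ".json")
  save_landscape(ls1, path)
  ls2 <- load_landscape(path)
  expect_identical(ls2$centers, ls1$centers)
  expect_identical(ls2$amplitudes, ls1$amplitudes)
  expect_identical(ls2$spreads, ls1$spreads)
  expect_identical(ls2$bounds, ls1$bounds)
  expect_identical(ls2$name, ls1$name)
  expect_error(load_landscape(withr::local_tempfile()), "not found")
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"format": 1, "name": "x"}', bad)
  expect_error(load_landscape(bad), "missing field 'dimensions'")
})

test_that("builtin model landscapes share geometry and order their spreads", {
  trio <- builtin_model_landscapes()
  expect_named(trio, c("smooth", "medium", "rugged"))
  expect_identical(trio$smooth$centers, trio$rugged$centers)
  expect_identical(trio$smooth$amplitudes, trio$medium$amplitudes)
  expect_true(all(trio$smooth$spreads > trio$medium$spreads))
  expect_true(all(trio$medium$spreads > trio$rugged$spreads))
  for (l in trio) expect_equal(unname(l$bounds), rbind(c(0, 0), c(1000, 1000)))
})

test_that("supplementary surface import honors its error and format contracts", {
  expect_error(import_supplementary_surface("no/such/surface_matrix-low.py"),
               "supplementary file required")
  # documented layout 1: list of (amp, cx, cy, sx, sy) tuples
  f1 <- withr::local_tempfile(fileext = ".py")
  writeLines(c("import numpy as np",
               "peaks = [(10.0, 620.0, 410.0, 90.5, 75.0),",
               "         (7.5, 220.0, 750.0, 70.0, 85.0)]"), f1)
  ls1 <- import_supplementary_surface(f1)
  expect_equal(nrow(ls1$centers), 2)
  expect_equal(ls1$amplitudes, c(10, 7.5))
  expect_equal(ls1$centers[1, ], c(620, 410))
  expect_equal(ls1$spreads[2, ], c(70, 85))
  # documented layout 2: explicit Gaussian terms
  f2 <- withr::local_tempfile(fileext = ".py")
  writeLines(c("import numpy as np",
               "Z = 4.5*np.exp(-((X-850)**2/(2*75**2) + (Y-250)**2/(2*60**2)))",
               "Z += 3.5 * np.exp(-((X - 650)**2 / (2*60**2) + (Y - 850)**2 / (2*70**2)))"),
             f2)
  ls2 <- import_supplementary_surface(f2)
  expect_equal(ls2$amplitudes, c(4.5, 3.5))
  expect_equal(ls2$centers, rbind(c(850, 250), c(650, 850)))
  expect_equal(ls2$spreads, rbind(c(75, 60), c(60, 70)))
  # unparseable content is a format error, not a crash
  f3 <- withr::local_tempfile(fileext = ".py")
  writeLines("print('no surface here')", f3)
  expect_error(import_supplementary_surface(f3), "cannot parse")
})

test_that("grid export writes a full-precision coordinate table", {
  g <- grid_sample(single_peak(), 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_grid_tsv(g, path)
  tab <- read.delim(path)
  expect_named(tab, c("x1", "x2", "fitness"))
  expect_equal(tab$fitness, g$fitnesses, tolerance = 1e-15)
})
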