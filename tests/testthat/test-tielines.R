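# Forward-construction oracle: pick two points ON a known binodal, mix them
# with the lever rule at a chosen alpha, and check the solver recovers the
# endpoints from (mixture, alpha) alone.

forward_case <- function(model, x_il, x_non, alpha) {
  y_il <- evaluate_binodal(model, x_il)
  y_non <- evaluate_binodal(model, x_non)
  list(
    x_m = alpha * x_il + (1 - alpha) * x_non,
    y_m = alpha * y_il + (1 - alpha) * y_non,
    il_rich = c(x = x_il, y = y_il),
    non_il_rich = c(x = x_non, y = y_non),
    alpha = alpha
  )
}

test_that("solver recovers forward-constructed endpoints to 1e-8", {
  m <- binodal_model(80, -0.3, 5e-5)
  case <- forward_case(m, x_il = 1, x_non = 15, alpha = 0.6)
  tl <- solve_tieline(tieline_problem(m, case$x_m, case$y_m, case$alpha))
  expect_equal(tl$il_rich, case$il_rich, tolerance = 1e-8)
  expect_equal(tl$non_il_rich, case$non_il_rich, tolerance = 1e-8)
  expect_lt(tl$residual, 1e-8)
  # IL-rich endpoint is the one with larger IL content
  expect_gt(tl$il_rich[["y"]], tl$non_il_rich[["y"]])
})

test_that("100 random forward constructions close the lever rule to 1e-10", {
  set.seed(101)
  worst_endpoint <- 0; worst_balance <- 0
  n_done <- 0
  while (n_done < 100) {
    m <- binodal_model(runif(1, 60, 100), runif(1, -0.5, -0.15),
                       runif(1, 1e-5, 1e-4))
    case <- forward_case(m, x_il = runif(1, 0.2, 3),
                         x_non = runif(1, 8, 30),
                         alpha = runif(1, 0.2, 0.8))
    comp <- validate_composition(case$y_m, case$x_m,
                                 100 - case$x_m - case$y_m)
    if (classify_mixture(m, comp) != "biphasic") next
    tl <- solve_tieline(tieline_problem(m, case$x_m, case$y_m, case$alpha))
    worst_endpoint <- max(worst_endpoint,
                          abs(tl$il_rich - case$il_rich),
                          abs(tl$non_il_rich - case$non_il_rich))
    mix_back <- case$alpha * tl$il_rich + (1 - case$alpha) * tl$non_il_rich
    worst_balance <- max(worst_balance,
                         abs(mix_back - c(case$x_m, case$y_m)))
    n_done <- n_done + 1
  }
  expect_lt(worst_endpoint, 1e-8)
  expect_lt(worst_balance, 1e-10)
})

test_that("tie-lines sharing a binodal do not cross", {
  m <- binodal_model(80, -0.3, 5e-5)
  # nested mixtures along a dilution line
  tls <- lapply(c(0.45, 0.55, 0.65), function(s) {
    case <- forward_case(m, x_il = 2 * (1 - s) + 0.3, x_non = 10 + 15 * s,
                         alpha = 0.5)
    solve_tieline(tieline_problem(m, case$x_m, case$y_m, 0.5))
  })
  segs <- lapply(tls, function(tl) rbind(tl$il_rich, tl$non_il_rich))
  cross <- function(a, b) {
    d <- function(p, q, r) {
      (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
    }
    d1 <- d(a[1, ], a[2, ], b[1, ]); d2 <- d(a[1, ], a[2, ], b[2, ])
    d3 <- d(b[1, ], b[2, ], a[1, ]); d4 <- d(b[1, ], b[2, ], a[2, ])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in 1:2) for (j in (i + 1):3) {
    expect_false(cross(segs[[i]], segs[[j]]))
  }
})

test_that("degenerate problems are rejected", {
  m <- binodal_model(80, -0.3, 5e-5)
  # monophasic mixture
  expect_error(tieline_problem(m, x_m = 2, y_m = 10, alpha = 0.5),
               "monophasic")
  # mixture on the binodal (alpha -> 1 lever degeneracy)
  y_on <- evaluate_binodal(m, 5)
  expect_error(tieline_problem(m, x_m = 5, y_m = y_on, alpha = 0.999),
               "on_curve")
  expect_error(tieline_problem(m, 6, 45, alpha = 1), "alpha")
})

test_that("tie-line metrics match hand arithmetic and symmetries", {
  tl <- list(il_rich = c(x = 10, y = 50), non_il_rich = c(x = 30, y = 5))
  met <- tieline_metrics(tl)
  expect_equal(unname(met[["length"]]), sqrt(400 + 2025), tolerance = 1e-12)
  expect_equal(unname(met[["slope"]]), -2.25, tolerance = 1e-12)

  swapped <- tieline_metrics(list(il_rich = tl$non_il_rich,
                                  non_il_rich = tl$il_rich))
  expect_equal(met[["length"]], swapped[["length"]])
  expect_equal(met[["slope"]], swapped[["slope"]])

  same <- tieline_metrics(list(il_rich = c(x = 3, y = 4),
                               non_il_rich = c(x = 3, y = 4)))
  expect_identical(unname(same[["length"]]), 0)

  vert <- tieline_metrics(list(il_rich = c(x = 3, y = 9),
                               non_il_rich = c(x = 3, y = 4)))
  expect_identical(unname(vert[["slope"]]), Inf)
  expect_true(isTRUE(attr(vert, "vertical")))
})

test_that("lever-rule alpha reproduces the measured phase split", {
  # IL contents of the coexisting phases of a K3PO4 system whose mixture
  # held 30 wt% IL: alpha = (30 - 4.2344) / (54.0350 - 4.2344)
  res <- lever_rule_alpha(c(x = 3, y = 30),
                          c(x = 0.3349, y = 54.0350),
                          c(x = 6.7525, y = 4.2344))
  expect_equal(res$alpha_y, 0.517375, tolerance = 1e-4)

  p <- c(x = 2, y = 50); q <- c(x = 12, y = 10)
  at_p <- lever_rule_alpha(p, p, q)
  expect_equal(at_p$alpha_y, 1)
  expect_equal(at_p$alpha_x, 1)
  mid <- lever_rule_alpha((p + q) / 2, p, q)
  expect_equal(mid$alpha, 0.5, tolerance = 1e-12)
  expect_lt(mid$closure, 1e-12)

  # coincident endpoints on one axis are skipped
  res2 <- lever_rule_alpha(c(x = 5, y = 30), c(x = 5, y = 50),
                           c(x = 5, y = 10))
  expect_true(is.na(res2$alpha_x))
  expect_equal(res2$alpha_y, 0.5)
  expect_error(lever_rule_alpha(c(x = 1, y = 1), c(x = 2, y = 3),
                                c(x = 2, y = 3)), "distinct")
})
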