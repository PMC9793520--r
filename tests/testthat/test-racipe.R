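test_that("the shifted Hill function hits its analytic anchors and bounds", {
  expect_equal(shifted_hill(50, 50, 3, 10), (1 + 10) / 2)
  expect_equal(shifted_hill(7, 50, 3, 1), 1)
  expect_equal(shifted_hill(2 * 50, 50, 2, 0.1), 0.1 + 0.9 / 5)
  x <- seq(0, 500, by = 5)
  for (lam in c(0.05, 20)) {
    h <- shifted_hill(x, 50, 4, lam)
    expect_true(all(h >= min(1, lam) - 1e-12 & h <= max(1, lam) + 1e-12))
    expect_equal(h[1], 1)
  }
})

test_that("sampled kinetic parameters respect their declared ranges", {
  topo <- topology(data.frame(source = c("A", "B", "A"),
                              target = c("B", "A", "C"),
                              type = c("excitatory", "inhibitory",
                                       "signaling_inhibitory")))
  nm <- estimate_node_medians(topo)
  set.seed(1)
  draws <- lapply(1:2000, function(i)
    sample_model(topo, node_medians = nm))
  G <- unlist(lapply(draws, `[[`, "G"))
  k <- unlist(lapply(draws, `[[`, "k"))
  h <- unlist(lapply(draws, function(p) p$edges$h))
  expect_true(all(G >= 1 & G <= 100))
  expect_true(all(k >= 0.1 & k <= 1))
  expect_true(all(h %in% 1:6))
  expect_equal(mean(h), 3.5, tolerance = 3 * sd(h) / sqrt(length(h)) / 3.5)
  lam_exc <- unlist(lapply(draws, function(p)
    p$edges$lam[p$edges$type == "excitatory"]))
  lam_inh <- unlist(lapply(draws, function(p)
    p$edges$lam[p$edges$type != "excitatory"]))
  expect_true(all(lam_exc >= 1 & lam_exc <= 100))
  expect_true(all(lam_inh >= 0.01 & lam_inh <= 1))
  for (nd in c("A", "B")) {
    X0 <- unlist(lapply(draws, function(p)
      p$edges$X0[p$edges$source == nd]))
    expect_true(all(X0 >= 0.02 * nm[nd] & X0 <= 1.98 * nm[nd]))
  }
  expect_identical(sample_model(topo, seed = 9, node_medians = nm),
                   sample_model(topo, seed = 9, node_medians = nm))
})

test_that("an unregulated gene settles at G/k to six digits", {
  topo <- topology(data.frame(source = "A", target = "B",
                              type = "excitatory"))
  p <- sample_model(topo, seed = 31)
  ss <- steady_states(topo, p, n_inits = 3, seed = 1)
  expect_gt(length(ss$states), 0L)
  for (st in ss$states)
    expect_equal(st$x[["A"]], unname(p$G["A"] / p$k["A"]),
                 tolerance = 1e-6)
})

test_that("recorded states pass an independent residual re-check", {
  grn <- synthetic_grn(n_tf = 5, targets_per_tf = 4, n_pool = 30,
                       seed = 3)
  ens <- simulate_ensemble(grn$topology, n_models = 4, n_inits = 2,
                           seed = 8, protein_noise = 1)
  found <- 0L
  for (m in ens$models) for (st in m$states) {
    expect_lt(naive_residual(m$params, st$x), 1e-6)
    found <- found + 1L
  }
  expect_gt(found, 0L)
})

test_that("a strongly self-activating gene is bistable", {
  topo <- topology(data.frame(source = "A", target = "A",
                              type = "excitatory"))
  p <- fixed_params(topo, G = 10, k = 1, h = 4, lam = 10, X0 = 50)
  ss <- steady_states(topo, p, n_inits = 40, seed = 2)
  lv <- sort(vapply(ss$states, function(s) s$x[["A"]], numeric(1)))
  expect_identical(length(lv), 2L)
  # nullcline: low state near G/k (self-activation off), high near lam*G/k
  expect_equal(lv[1], 10, tolerance = 0.1)
  expect_equal(lv[2], 100, tolerance = 0.1)
})

test_that("a mutual-inhibition toggle is bistable with mirror states", {
  topo <- topology(data.frame(source = c("A", "B"), target = c("B", "A"),
                              type = "inhibitory"))
  p <- fixed_params(topo, G = c(50, 50), k = c(0.5, 0.5), h = c(3, 3),
                    lam = c(0.02, 0.02), X0 = c(30, 30))
  ss <- steady_states(topo, p, n_inits = 40, seed = 4)
  expect_gte(length(ss$states), 2L)
  pat <- vapply(ss$states, function(s) s$x[["A"]] > s$x[["B"]], logical(1))
  expect_setequal(unique(pat), c(TRUE, FALSE))
})

test_that("knockdowns pair with the unperturbed ensemble and act on G", {
  topo <- topology(data.frame(source = c("A", "B"), target = c("B", "A"),
                              type = "inhibitory"))
  wt <- simulate_ensemble(topo, n_models = 10, n_inits = 5, seed = 6)
  same <- knockdown_ensemble(topo, "A", kd_factor = 1, n_models = 10,
                             n_inits = 5, seed = 6)
  expect_equal(same$models, wt$models, tolerance = 1e-12)

  deep <- knockdown_ensemble(topo, "A", kd_factor = 1e-4, n_models = 10,
                             n_inits = 5, seed = 6)
  xa <- unlist(lapply(deep$models, function(m)
    vapply(m$states, function(s) s$x[["A"]], numeric(1))))
  expect_true(all(xa < 0.1))
  expect_error(knockdown_ensemble(topo, "Z", n_models = 2, n_inits = 1),
               "not in topology")
})

test_that("ensembles are byte-identical at a fixed seed", {
  topo <- topology(data.frame(source = c("A", "B"), target = c("B", "A"),
                              type = c("excitatory", "inhibitory")))
  e1 <- simulate_ensemble(topo, n_models = 5, n_inits = 3, seed = 12)
  e2 <- simulate_ensemble(topo, n_models = 5, n_inits = 3, seed = 12)
  expect_identical(e1$models, e2$models)
})

test_that("signaling input changes a TF's activity but not its expression", {
  # C --sig--> A --trans--> B ; A itself unregulated transcriptionally
  topo <- topology(data.frame(source = c("C", "A"),
                              target = c("A", "B"),
                              type = c("signaling_inhibitory",
                                       "excitatory")))
  p <- fixed_params(topo, G = c(40, 30, 20), k = c(0.5, 0.5, 0.5),
                    h = c(3, 3), lam = c(0.05, 8), X0 = c(40, 60))
  lo <- steady_states(topo, p, n_inits = 2, seed = 1,
                      clamp = list(gene = "C", level = 1))
  hi <- steady_states(topo, p, n_inits = 2, seed = 1,
                      clamp = list(gene = "C", level = 400))
  expect_equal(lo$states[[1]]$x[["A"]], hi$states[[1]]$x[["A"]],
               tolerance = 1e-5)
  expect_gt(lo$states[[1]]$a[["A"]], hi$states[[1]]$a[["A"]])
  # B reads A's activity, so B's expression follows the signaling input
  expect_gt(lo$states[[1]]$x[["B"]], hi$states[[1]]$x[["B"]])
})

test_that("a clamped regulator drives its target along the Hill response", {
  topo <- topology(data.frame(source = "A", target = "B",
                              type = "excitatory"))
  p <- fixed_params(topo, G = c(10, 40), k = c(1, 0.8), h = 2, lam = 6,
                    X0 = 25)
  for (lv in c(0, 5, 25, 80, 300)) {
    ss <- steady_states(topo, p, n_inits = 1, seed = 1,
                        clamp = list(gene = "A", level = lv))
    expect_equal(ss$states[[1]]$x[["B"]],
                 40 * shifted_hill(lv, 25, 2, 6) / 0.8,
                 tolerance = 1e-5)
  }
})

test_that("a bifurcation sweep shows a bistable window in a toggle", {
  topo <- topology(data.frame(source = c("A", "B"), target = c("B", "A"),
                              type = "inhibitory"))
  sw <- bifurcation_sweep(topo, "A", levels = c(0.1, 30, 2000),
                          n_models = 8, n_inits = 6, seed = 10)
  n_states <- vapply(sw$ensembles, function(e)
    sum(vapply(e$models, function(m) length(m$states), integer(1))),
    integer(1))
  expect_true(all(n_states > 0))
  expect_identical(nrow(sw$projection), sum(n_states))
  # clamping A very high forces B off in every model: one state each
  multi_hi <- vapply(sw$ensembles[[3]]$models, function(m)
    length(m$states), integer(1))
  expect_true(all(multi_hi == 1L))
})

test_that("state classification maps to the nearest reference profile", {
  set.seed(15)
  ref <- matrix(rnorm(30), 10, 3,
                dimnames = list(paste0("g", 1:10), c("E", "H", "M")))
  expect_identical(classify_states(ref, ref), c("E", "H", "M"))
  anti <- -ref[, c(1, 3)]
  colnames(anti) <- c("E", "M")
  expect_identical(classify_states(anti, ref[, c(1, 3)]), c("M", "E"))

  centers <- matrix(rnorm(20, sd = 2), 10, 2,
                    dimnames = list(paste0("g", 1:10), c("c1", "c2")))
  states <- centers[, rep(1:2, each = 50)] + rnorm(1000, sd = 0.4)
  lab <- classify_states(states, centers)
  expect_gte(mean(lab == rep(c("c1", "c2"), each = 50)), 0.95)

  expect_error(classify_states(ref[1:2, ], ref), "fewer than 3")
})

test_that("topology files round-trip with signed signaling codes", {
  topo <- topology(data.frame(source = c("A", "B", "C", "C"),
                              target = c("B", "C", "A", "B"),
                              type = c(1, 2, 3, 4)))
  expect_identical(topo$type[3], "signaling_excitatory")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_topology(topo, path)
  back <- read_topology(path)
  expect_identical(back$type, topo$type)
  expect_error(topology(data.frame(source = "A", target = "B", type = 9)),
               "edge types")
})
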