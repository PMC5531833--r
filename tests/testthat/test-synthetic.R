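test_that("pacemaker traces obey the planted phase structure", {
  sim <- gen_pacemaker_traces(2, 2, period = 71, duty = 0.5, rate = 1.5,
                              noise_sd = 0, duration = 426, seed = 6)
  expect_equal(pearson(sim$traces[[1]], sim$traces[[2]]), 1)
  expect_lt(pearson(sim$traces[[1]], sim$traces[[3]]), 0)
  est <- cycle_length(sim$traces[[1]])
  bin <- 1.5 / length(sim$traces[[1]]$values)
  expect_lte(abs(est$frequency - 1 / 71), bin)
  expect_error(gen_pacemaker_traces(1, 0, period = 4, rate = 1), "under-resolved")
})

test_that("generators are bit-reproducible given parameters and seed", {
  a <- gen_pacemaker_traces(2, 1, noise_sd = 3, seed = 9)
  b <- gen_pacemaker_traces(2, 1, noise_sd = 3, seed = 9)
  expect_identical(a, b)
  k1 <- gen_kymograph(15, noise_sd = 5, seed = 4)
  k2 <- gen_kymograph(15, noise_sd = 5, seed = 4)
  expect_identical(k1$kymograph$grid, k2$kymograph$grid)
  g1 <- gen_planted_connectome(c(5, 5), seed = 3)
  g2 <- gen_planted_connectome(c(5, 5), seed = 3)
  expect_identical(g1$network$edges, g2$network$edges)
})

test_that("movies round trip exactly at zero noise and recover drift", {
  sim <- gen_pacemaker_traces(1, 1, period = 40, rate = 1, noise_sd = 0,
                              duration = 80, seed = 2)
  scene <- list(centers = rbind(c(8, 8), c(24, 24)), radii = c(5, 5),
                frame_size = c(32, 32), background = 50, noise_sd = 0,
                drift = c(0, 0))
  gm <- gen_movie(sim$traces, scene, seed = 1)
  got <- extract_trace(gm$movie, gm$masks[[1]])
  expect_equal(got$values, sim$traces[[1]]$values)

  short <- lapply(sim$traces, function(tr) trace(tr$values[1:5], tr$rate))
  scene$drift <- c(1, 0)
  gm2 <- gen_movie(short, scene, seed = 1)
  mc <- motion_correct(gm2$movie, max_shift = 6)
  expect_equal(mc$shifts[, "dy"], -(0:4))

  scene$centers <- rbind(c(8, 8), c(10, 8))
  expect_error(gen_movie(short, scene, seed = 1), "overlap")
})

test_that("correlation maps recover phase classes from noisy movies", {
  sim <- gen_pacemaker_traces(1, 1, period = 71, rate = 1.5, noise_sd = 0,
                              duration = 426, seed = 3)
  scene <- list(centers = rbind(c(9, 9), c(23, 23)), radii = c(5, 5),
                frame_size = c(32, 32), background = 80, noise_sd = 6,
                drift = c(0, 0))
  gm <- gen_movie(sim$traces, scene, seed = 5)
  ref <- extract_trace(gm$movie, gm$masks[[1]])
  cm <- correlation_map(gm$movie, ref)
  sign_ok <- c(cm$r[gm$masks[[1]]] > 0, cm$r[gm$masks[[2]]] < 0)
  expect_gte(mean(sign_ok), 0.99)
})

test_that("kymograph generator plants recoverable structure", {
  # arrest placed so the longest beating segment (320 frames) keeps the
  # 15 Hz beat bin-aligned
  gk <- gen_kymograph(15, arrests = data.frame(start = 200, end = 281),
                      rate = 60, n_frames = 600, noise_sd = 0)
  det <- detect_arrests(gk$kymograph, std_window = 9)
  expect_gte(jaccard_frames(det, gk$arrests, 600), 0.95)
  bf <- beat_frequency(gk$kymograph, gk$arrests)
  expect_equal(bf$frequency, 15)
  expect_error(gen_kymograph(40, rate = 60), "Nyquist")
})

test_that("noise degrades recovery monotonically in expectation", {
  jac_at <- function(noise_sd) {
    mean(vapply(1:5, function(s) {
      gk <- gen_kymograph(15, arrests = data.frame(start = c(100, 400),
                                                   end = c(160, 470)),
                          rate = 60, n_frames = 600, noise_sd = noise_sd,
                          seed = s)
      jaccard_frames(detect_arrests(gk$kymograph, std_window = 9),
                     gk$arrests, 600)
    }, numeric(1)))
  }
  j <- vapply(c(5, 20, 60), jac_at, numeric(1))
  expect_true(all(diff(j) <= 0.02))   # 5-seed means: small sampling slack
  expect_lt(j[3], j[1])
  # sign recovery in correlation maps degrades with pixel noise too
  sim <- gen_pacemaker_traces(1, 1, period = 71, rate = 1.5, noise_sd = 0,
                              duration = 213, seed = 4)
  rec_at <- function(noise_sd) {
    mean(vapply(1:3, function(s) {
      scene <- list(centers = rbind(c(9, 9), c(23, 23)), radii = c(5, 5),
                    frame_size = c(32, 32), background = 80,
                    noise_sd = noise_sd, drift = c(0, 0))
      gm <- gen_movie(sim$traces, scene, seed = s)
      cm <- correlation_map(gm$movie, extract_trace(gm$movie, gm$masks[[1]]))
      mean(c(cm$r[gm$masks[[1]]] > 0, cm$r[gm$masks[[2]]] < 0))
    }, numeric(1)))
  }
  rec <- vapply(c(5, 500, 5000), rec_at, numeric(1))
  expect_true(all(diff(rec) <= 0.02))
  expect_lt(rec[3], rec[1])
})

test_that("planted connectomes are recovered and flag degeneracy", {
  iso <- gen_planted_connectome(c(6, 6), p_out = 0, seed = 2)
  part <- detect_modules(iso$network, seed = 2)
  expect_equal(adjusted_rand(part$assignment[names(iso$partition)],
                             iso$partition), 1)
  one <- gen_planted_connectome(c(8), p_out = 0, seed = 1)
  p1 <- detect_modules(one$network, resolution = 1, seed = 1)
  expect_equal(p1$n_modules, 1)
  expect_false(iso$degenerate)
  expect_true(gen_planted_connectome(c(4, 4), p_in = 0.3, p_out = 0.5,
                                     seed = 1)$degenerate)
})

test_that("the connectome fixture reproduces the published census", {
  net <- make_paper_fixture()
  mc_cells <- net$nodes[net$nodes$cell_class == "multiciliated", ]
  expect_equal(nrow(mc_cells), 80)   # 23+8+6+1+8+8+14+12
  counts <- table(mc_cells$group)
  expect_equal(unname(counts[c("prototroch", "akrotroch", "nuchal",
                               "crescent", "metatroch", "paratroch_I",
                               "paratroch_II", "paratroch_III")]),
               c(23, 8, 6, 1, 8, 8, 14, 12), ignore_attr = TRUE)
  mc_out <- net$edges[net$edges$pre == "MC", ]
  expect_equal(sum(mc_out$weight), 341)
  proto <- mc_cells$id[mc_cells$group == "prototroch"]
  onto_proto <- mc_out[mc_out$post %in% proto, ]
  expect_equal(sum(onto_proto$weight), 335)
  expect_setequal(onto_proto$post, proto)      # presynaptic to all 23
  expect_gte(min(onto_proto$weight), 3)
  expect_lte(max(onto_proto$weight), 25)
  expect_equal(range(onto_proto$weight), c(3, 25))
  expect_true("MC" %in% select_ciliomotor(net))
  # crescent cell: Loop neurons are its only input
  to_crescent <- net$edges[net$edges$post == "crescent_1", ]
  expect_setequal(to_crescent$pre, c("Loop_l", "Loop_r"))
})

test_that("the cohort generator plants the documented period distribution", {
  p <- mc_cohort_periods()
  expect_length(p, 96)
  expect_equal(median(p), 71)
  expect_equal(sum(p >= 50 & p <= 100), 41)
})
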