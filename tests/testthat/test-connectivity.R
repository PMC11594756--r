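test_that("a target train shifted by +5 ms gives the forced cumulative profile", {
  src <- c(100, 200, 300, 400, 500)
  s <- spike_train_set(list(m = src / 1000, n = (src + 5) / 1000), 10,
                       electrode_ids = c("m", "n"))
  b <- detect_network_bursts(s)
  pr <- pair_sync_profile(s, b, "m", "n", restrict = "none")
  expect_equal(pr$ratios[1:4], rep(0, 4))
  expect_equal(pr$ratios[5:50], rep(1, 46))
  expect_equal(pr$score, 1)
  expect_equal(pr$best_delay_ms, 5L)

  # empty source -> all zero, score 0
  s2 <- spike_train_set(list(m = numeric(0), n = src / 1000), 10,
                        electrode_ids = c("m", "n"))
  pr2 <- pair_sync_profile(s2, detect_network_bursts(s2), "m", "n", restrict = "none")
  expect_equal(sum(pr2$counts), 0L)
  expect_equal(pr2$score, 0)
  expect_true(is.na(pr2$best_delay_ms))
  # target with no spikes -> score 0, not an error
  pr3 <- pair_sync_profile(s2, detect_network_bursts(s2), "n", "m", restrict = "none")
  expect_equal(pr3$score, 0)

  expect_error(pair_sync_profile(s2, detect_network_bursts(s2), "m", "m"),
               "differ")
})

test_that("profile counts equal the nested-loop oracle and are cumulative", {
  for (seed in 1:20) {
    src <- random_train_ms(seed, sample(30:120, 1))
    tgt <- random_train_ms(seed + 1000, sample(30:120, 1))
    s <- spike_train_set(list(m = src / 1000, n = tgt / 1000), 2,
                         electrode_ids = c("m", "n"))
    pr <- pair_sync_profile(s, detect_network_bursts(s), "m", "n",
                            restrict = "none")
    expect_equal(pr$counts, oracle_sync_counts(src, tgt))
    expect_true(all(diff(pr$counts) >= 0L))       # nondecreasing in k
    expect_true(all(pr$ratios >= 0 & pr$ratios <= 1))
  }
})

test_that("in-burst restriction drops spikes outside large-burst spans", {
  g <- generate_recording(recovery_config(seed = 4, duration_s = 60))
  b <- detect_network_bursts(g$recording)
  r <- restrict_to_bursts(g$recording, b, "large")
  spans <- b[b$size_class == "large", ]
  inside <- function(t) any(t >= spans$start_s - 1e-12 & t <= spans$end_s + 1e-12)
  for (id in r$electrode_ids) {
    expect_true(all(vapply(r$spikes[[id]], inside, logical(1))))
  }
  expect_lte(n_spikes(r), n_spikes(g$recording))
})

test_that("pair ranking is deterministic and permutation-invariant", {
  profiles <- data.frame(
    m = c("a", "b", "c", "d"), n = c("b", "c", "d", "a"),
    score = c(0.5, 0.9, 0.5, 0.2),
    best_delay_ms = c(7L, 4L, 3L, 2L))
  rk <- rank_pairs(profiles)
  expect_equal(rk$score, c(0.9, 0.5, 0.5, 0.2))
  # tie at 0.5 broken by smaller half-rise delay
  expect_equal(rk$m[2:3], c("c", "a"))

  set.seed(1)
  big <- data.frame(
    m = sprintf("m%02d", 1:40), n = sprintf("n%02d", 1:40),
    score = round(runif(40), 2), best_delay_ms = sample(1:50, 40, replace = TRUE))
  r1 <- rank_pairs(big)
  r2 <- rank_pairs(big[sample(40), ])
  expect_equal(r1, r2)
  # matches an independent sort oracle on distinct scores
  distinct <- big[!duplicated(big$score), ]
  expect_equal(rank_pairs(distinct)$score, sort(distinct$score, decreasing = TRUE))
})

test_that("the top-5% selection rule sizes the edge set by ceiling over positive scores", {
  mk_profiles <- function(n_pos, n_zero = 10) {
    pairs <- expand.grid(m = sprintf("p%02d", 1:20), n = sprintf("q%02d", 1:20),
                         stringsAsFactors = FALSE)[seq_len(n_pos + n_zero), ]
    pairs$score <- c(seq(1, 0.01, length.out = n_pos), rep(0, n_zero))
    pairs$best_delay_ms <- rep(1:10, length.out = nrow(pairs))
    pairs
  }
  # 100 positive pairs -> exactly 5 edges, the 5 largest scores
  cg <- build_connectivity_graph(rank_pairs(mk_profiles(100)))
  expect_equal(nrow(cg$edges), 5L)
  expect_equal(sort(cg$edges$score, decreasing = TRUE),
               sort(mk_profiles(100)$score, decreasing = TRUE)[1:5])
  # 63 positive pairs -> ceiling(3.15) = 4 edges
  expect_equal(nrow(build_connectivity_graph(rank_pairs(mk_profiles(63)))$edges), 4L)
  # all scores zero -> empty graph with diameter 0
  cg0 <- build_connectivity_graph(rank_pairs(mk_profiles(0, 25)))
  expect_equal(nrow(cg0$edges), 0L)
  expect_equal(hub_metrics(cg0)$diameter, 0)
  expect_true(is.na(hub_metrics(cg0)$hub_coefficient))
})

test_that("hub metrics recover forced geometries and match the shortest-path oracle", {
  # star: centre -> 6 leaves
  star <- data.frame(m = "hub", n = paste0("l", 1:6),
                     score = seq(0.9, 0.4, by = -0.1), best_delay_ms = 1:6)
  cg <- build_connectivity_graph(rank_pairs(star), top_fraction = 1)
  hm <- hub_metrics(cg)
  expect_equal(hm$hubs, "hub")
  expect_equal(hm$hub_coefficient, 6)
  expect_equal(hm$diameter, 2)

  # random sparse graphs: diameter equals brute-force all-pairs BFS
  for (seed in 1:5) {
    set.seed(seed)
    nodes <- sprintf("v%02d", 1:20)
    ed <- unique(data.frame(m = sample(nodes, 30, replace = TRUE),
                            n = sample(nodes, 30, replace = TRUE)))
    ed <- ed[ed$m != ed$n, ]
    ed$score <- runif(nrow(ed), 0.1, 1)
    ed$best_delay_ms <- sample(1:50, nrow(ed), replace = TRUE)
    cg <- build_connectivity_graph(rank_pairs(ed), top_fraction = 1)
    expect_equal(hub_metrics(cg)$diameter, oracle_diameter(ed))
  }
})

test_that("removing an electrode's spikes removes its incident edges", {
  g <- generate_recording(recovery_config(seed = 6, duration_s = 120))
  s <- g$recording
  b <- detect_network_bursts(s)
  cg_full <- build_connectivity_graph(rank_pairs(pair_sync_profiles(s, b)))
  victim <- cg_full$edges$n[1]   # a target node with at least one incident edge
  expect_true(victim %in% c(cg_full$edges$m, cg_full$edges$n))

  spk <- s$spikes
  spk[[victim]] <- numeric(0)
  s2 <- spike_train_set(spk, s$duration_s, electrode_ids = s$electrode_ids)
  b2 <- detect_network_bursts(s2)
  cg2 <- build_connectivity_graph(rank_pairs(pair_sync_profiles(s2, b2)))
  expect_false(victim %in% c(cg2$edges$m, cg2$edges$n))
})
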