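# Fixture: a 600 s recording containing exactly one small burst (10 spikes
# over 30 ms), one large burst (120 spikes over ~40 ms), and 30 stray
# background spikes on a single electrode, 1 s apart, far from both bursts.
make_two_burst_fixture <- function() {
  ids <- paste0("e", 1:12)
  spk <- stats::setNames(rep(list(numeric(0)), 12), ids)
  small_t <- 100 + (0:9) * 30e-3 / 9            # 10 spikes over 30 ms
  small_el <- rep(ids[1:5], length.out = 10)
  large_t <- 300 + (0:119) * 0.000333           # 120 spikes over ~40 ms
  large_el <- rep(ids, length.out = 120)
  stray_t <- 400 + 0:29                         # 30 strays, 1 s apart
  for (i in seq_along(small_t)) spk[[small_el[i]]] <- c(spk[[small_el[i]]], small_t[i])
  for (i in seq_along(large_t)) spk[[large_el[i]]] <- c(spk[[large_el[i]]], large_t[i])
  spk[["e1"]] <- c(spk[["e1"]], stray_t)
  spike_train_set(spk, 600, electrode_ids = ids, recording_id = "fixture")
}

test_that("the five activity parameters match a hand count on a two-burst fixture", {
  s <- make_two_burst_fixture()
  b <- detect_network_bursts(s)
  expect_equal(nrow(b), 2L)
  expect_equal(sort(b$size_class), c("large", "small"))

  st <- compute_burst_statistics(s, b)
  expect_equal(st$n_small_per_min, 0.1)
  expect_equal(st$n_large_per_min, 0.1)
  expect_equal(st$mean_spikes_small, 10)
  expect_equal(st$mean_spikes_large, 120)
  expect_equal(st$pct_spikes_in_bursts, 100 * 130 / 160)
  expect_equal(st$mean_amplitude_large, 120)
  expect_equal(st$mean_duration_small_ms, 30, tolerance = 1e-6)
})

test_that("proportion of spikes in bursts spans its closed bounds", {
  # every spike inside a burst -> 100%
  s <- spike_train_set(list(e1 = 0.000, e2 = 0.010, e3 = 0.020, e4 = 0.030), 60)
  st <- compute_burst_statistics(s, detect_network_bursts(s))
  expect_equal(st$pct_spikes_in_bursts, 100)

  # spikes but no bursts -> 0%
  s0 <- spike_train_set(list(e1 = c(1, 5, 9)), 60, electrode_ids = paste0("e", 1:4))
  st0 <- compute_burst_statistics(s0, detect_network_bursts(s0))
  expect_equal(st0$pct_spikes_in_bursts, 0)
  expect_true(is.na(st0$mean_spikes_small))   # missing, not zero

  # no spikes at all -> rates 0, proportion missing
  se <- spike_train_set(list(), 60, electrode_ids = paste0("e", 1:4))
  ste <- compute_burst_statistics(se, detect_network_bursts(se))
  expect_equal(ste$n_small_per_min + ste$n_large_per_min, 0)
  expect_true(is.na(ste$pct_spikes_in_bursts))
})

test_that("spike conservation holds on fuzzed recordings", {
  for (seed in 1:10) {
    s <- random_bursty_set(seed, n_electrodes = 8, n_spikes = 400, duration_s = 5)
    b <- detect_network_bursts(s)
    st <- compute_burst_statistics(s, b)
    expect_gte(st$pct_spikes_in_bursts, 0)
    expect_lte(st$pct_spikes_in_bursts, 100)
    # in-burst + out-of-burst = total, and bursts never double-count a spike
    n_in <- round(st$pct_spikes_in_bursts / 100 * st$n_spikes_total)
    expect_equal(n_in + (st$n_spikes_total - n_in), st$n_spikes_total)
    expect_equal(sum(b$total_spikes), n_in)
  }
})

test_that("minute-by-minute statistics cover every minute", {
  g <- generate_recording(synthetic_config(n_electrodes = 8, duration_s = 180,
                                           burst_rate_per_min = 6, seed = 2))
  bm <- burst_statistics_by_minute(g$recording)
  expect_equal(bm$minute, 1:3)
  expect_equal(sum(bm$n_spikes_total), n_spikes(g$recording))
})

test_that("longitudinal summaries compose per-recording statistics with baseline fold changes", {
  gl <- generate_longitudinal(
    schedule = data.frame(group = "Intact", div = c(14L, 21L), delta = 1),
    base_config = synthetic_config(n_electrodes = 8, duration_s = 60,
                                   burst_rate_per_min = 6),
    replicates = 2L, master_seed = 9L)
  sum_tab <- longitudinal_summary(gl$bundle)
  expect_equal(nrow(sum_tab), 4L)

  # composition identity: rows equal independently computed statistics
  id <- sum_tab$recording_id[1]
  s <- gl$bundle$recordings[[id]]
  st <- compute_burst_statistics(s, detect_network_bursts(s))
  expect_equal(sum_tab$pct_spikes_in_bursts[sum_tab$recording_id == id],
               st$pct_spikes_in_bursts)

  # bundle of one recording: fold change 1 against itself
  single <- recording_bundle(list(s))
  one <- longitudinal_summary(single)
  expect_equal(nrow(one), 1L)
  expect_equal(one$fc_pct_spikes_in_bursts, 1)

  # missing baseline DIV -> NA fold changes with a warning
  rec21 <- gl$bundle$recordings[gl$bundle$design$recording_id[gl$bundle$design$div == 21L]]
  expect_warning(no_base <- longitudinal_summary(recording_bundle(unname(rec21))),
                 "DIV14")
  expect_true(all(is.na(no_base$fc_pct_spikes_in_bursts)))
})
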