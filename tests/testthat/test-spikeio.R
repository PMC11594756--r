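test_that("spike_train_set validates its invariants", {
  s <- spike_train_set(list(e1 = c(0.3, 0.1), e2 = numeric(0)), 1)
  expect_equal(s$spikes$e1, c(0.1, 0.3))  # constructor sorts
  expect_equal(n_spikes(s), 2L)

  expect_error(spike_train_set(list(e1 = -0.1), 1), "negative")
  expect_error(spike_train_set(list(e1 = 2), 1), "duration")
  expect_error(spike_train_set(list(e1 = c(0.5, 0.5 + 1e-5)), 1), "duplicate")
  expect_error(spike_train_set(list(e1 = 0.1), 1, electrode_ids = c("e1", "e1")),
               "unique")
  # identical times on different electrodes are fine
  expect_silent(spike_train_set(list(e1 = 0.5, e2 = 0.5), 1))
  # silent electrodes can be declared in the layout
  s2 <- spike_train_set(list(e1 = 0.5), 1, electrode_ids = c("e1", "e2", "e3"))
  expect_equal(lengths(s2$spikes), c(e1 = 1L, e2 = 0L, e3 = 0L))
})

test_that("spike tables round-trip through disk", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "rec.csv")

  # 100-spike fixture
  set.seed(7)
  s <- random_bursty_set(7, n_electrodes = 5, n_spikes = 100, duration_s = 60)
  write_spike_table(s, p)
  r <- read_spike_table(p)
  expect_equal(r$electrode_ids, s$electrode_ids)
  expect_equal(r$duration_s, s$duration_s)
  for (id in s$electrode_ids) {
    expect_equal(r$spikes[[id]], s$spikes[[id]], tolerance = 1e-6)
  }

  # empty set round-trips
  e <- spike_train_set(list(), 600, electrode_ids = c("a", "b"))
  pe <- file.path(dir, "empty.csv")
  write_spike_table(e, pe)
  re <- read_spike_table(pe)
  expect_equal(n_spikes(re), 0L)
  expect_equal(re$duration_s, 600)
  expect_equal(re$electrode_ids, c("a", "b"))

  # synthetic 10-min recording (seed 1), field-by-field
  g <- generate_recording(synthetic_config(n_electrodes = 8, seed = 1,
                                           recording_id = "syn1"))
  ps <- file.path(dir, "syn.csv")
  write_spike_table(g$recording, ps)
  rs <- read_spike_table(ps)
  expect_equal(rs$electrode_ids, g$recording$electrode_ids)
  expect_equal(rs$meta$recording_id, "syn1")
  for (id in rs$electrode_ids) {
    expect_equal(rs$spikes[[id]], g$recording$spikes[[id]], tolerance = 1e-6)
  }
})

test_that("reader sorts, validates, and handles empty/missing metadata", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "x.csv")

  writeLines(c("e2,0.020", "e1,0.030", "e1,0.010"), p)
  s <- read_spike_table(p, duration_s = 600)
  expect_equal(s$spikes$e1, c(0.010, 0.030))
  expect_equal(n_spikes(s), 3L)

  writeLines(c("electrode_id,time_s", "e1,0.010", "e2,0.020"), p)
  expect_equal(n_spikes(read_spike_table(p, duration_s = 600)), 2L)

  writeLines("e1,-0.5", p)
  expect_error(read_spike_table(p, duration_s = 600), "negative")
  writeLines("e1,700.0", p)
  expect_error(read_spike_table(p, duration_s = 600), "duration")
  writeLines("e1,1.5", p)
  expect_warning(s3 <- read_spike_table(p), "duration")
  expect_gt(s3$duration_s, 1.5)

  writeLines(character(0), p)
  expect_equal(n_spikes(read_spike_table(p, duration_s = 600)), 0L)
})

test_that("split_minutes partitions the recording into re-zeroed segments", {
  g <- generate_recording(synthetic_config(n_electrodes = 6, duration_s = 600,
                                           burst_rate_per_min = 4, seed = 3))
  s <- g$recording
  segs <- split_minutes(s)
  expect_length(segs, 10L)
  expect_true(all(vapply(segs[1:9], function(x) x$duration_s, numeric(1)) == 60))
  # conservation: total spike count over segments equals the original
  expect_equal(sum(vapply(segs, n_spikes, integer(1))), n_spikes(s))

  # boundary convention: a spike exactly at 60 s lands in segment 2 at time 0
  b <- spike_train_set(list(e1 = c(10, 60), e2 = 61), 180)
  sb <- split_minutes(b)
  expect_length(sb, 3L)
  expect_equal(sb[[1]]$spikes$e1, 10)
  expect_equal(sb[[2]]$spikes$e1, 0)
  expect_equal(sb[[2]]$spikes$e2, 1)
  expect_equal(n_spikes(sb[[3]]), 0L)
})

test_that("bundles round-trip via manifest and validate their design", {
  gl <- generate_longitudinal(
    schedule = data.frame(group = c("Intact", "Ab"), div = 14L, delta = c(1, 0.5)),
    base_config = synthetic_config(n_electrodes = 6, duration_s = 30,
                                   burst_rate_per_min = 6),
    replicates = 2L, master_seed = 5L)
  dir <- withr::local_tempdir()
  manifest <- write_bundle(gl$bundle, dir)
  back <- read_bundle(manifest)
  expect_equal(back$design, gl$bundle$design)
  id <- gl$bundle$design$recording_id[1]
  expect_equal(n_spikes(back$recordings[[id]]), n_spikes(gl$bundle$recordings[[id]]))

  # malformed manifest is rejected with the offending field named
  bad <- file.path(dir, "bad.json")
  jsonlite::write_json(list(recordings = list(list(file = "x.csv"))), bad,
                       auto_unbox = TRUE)
  expect_error(read_bundle(bad), "recording_id")
  expect_error(recording_bundle(unname(gl$bundle$recordings),
                                allowed_divs = c(15L)), "DIV")
})
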