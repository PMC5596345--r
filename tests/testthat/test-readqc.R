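make_read <- function(id, len, q, seq = NULL) {
  data.frame(id = id, sample = "s1",
             sequence = if (is.null(seq))
               strrep("A", len) else seq,
             quality = strrep(intToUtf8(q + 33L), len),
             stringsAsFactors = FALSE)
}

test_that("expected error is the sum of per-base error probabilities", {
  expect_equal(expected_error(rep(20L, 369)), 3.69)
  expect_equal(expected_error(rep(40L, 369)), 0.0369)
  expect_equal(expected_error(0L), 1.0)
  # Phred+33 string input
  expect_equal(expected_error(strrep("I", 10)), 10 * 1e-4)
  expect_error(expected_error(integer(0)), "empty")
})

test_that("read filtering applies EE then inclusive length bounds", {
  reads <- rbind(
    make_read("short_good", 349, 40),  # fails length despite Q40
    make_read("len369_q20", 369, 20),  # EE 3.69 > 1 -> fails EE
    make_read("len380_q40", 380, 40),  # boundary length, retained
    make_read("len350_q40", 350, 40),  # boundary length, retained
    make_read("len381_q40", 381, 40))  # fails length
  out <- filter_reads(reads)
  expect_setequal(out$retained$id, c("len380_q40", "len350_q40"))
  rep_ <- out$report
  expect_equal(rep_$input, 5L)
  expect_equal(rep_$failed_ee, 1L)
  expect_equal(rep_$failed_length, 2L)
  expect_equal(rep_$retained, 2L)
  # every read tallied exactly once
  expect_equal(rep_$input,
               rep_$failed_ee + rep_$failed_length + rep_$spike +
                 rep_$retained)
})

test_that("spike identification is exact full-length matching", {
  sp <- spike_sequences(seed = 5)
  mismatch <- sp[1]
  substr(mismatch, 100, 100) <- if (substr(mismatch, 100, 100) == "A")
    "C" else "A"
  reads <- rbind(
    make_read("is_spike", 350, 38, seq = sp[1]),
    make_read("near_spike", 350, 38, seq = mismatch),
    make_read("other", 369, 38))
  out <- remove_spikes(reads, sp)
  expect_equal(unname(out$spike_counts[1, ]), c(1, 0, 0))
  expect_setequal(out$reads$id, c("near_spike", "other"))
})

test_that("QC on simulated reads recovers the simulator's spike draws", {
  ped <- sim_pedigree(n_generations = 2, mean_children = 0,
                      n_founder_couples = 3, seed = 1)
  cfg <- effect_config(read_depth = 800, sigma_genetic = 0,
                       depth_law = list(type = "fixed", depth = 2000),
                       frac_low_quality = 0.1, frac_short = 0.05)
  tab <- simulate_composition(ped, config = cfg, seed = 2)
  sp <- spike_sequences()
  reads <- simulate_reads(tab, sp, cfg, seed = 3)
  qc <- qc_reads(reads, sp)
  truth <- attr(reads, "spike_draws")
  expect_equal(qc$spike_counts[rownames(truth), ], truth,
               ignore_attr = TRUE)
  rep_ <- qc$report
  expect_equal(rep_$input,
               rep_$failed_ee + rep_$failed_length + rep_$spike +
                 rep_$retained)
})

test_that("depth filter removes, caps, and is idempotent", {
  counts <- rbind(low = c(4999L, 0L), mid = c(5000L, 5000L),
                  high = c(20000L, 5000L))
  colnames(counts) <- c("p1", "p2")
  tab <- phylotype_table(counts)
  out <- depth_filter_subsample(tab, seed = 1)
  expect_false("low" %in% rownames(out$counts))
  expect_equal(sum(out$counts["high", ]), 20000)
  expect_equal(out$counts["mid", ], counts["mid", ])
  again <- depth_filter_subsample(out, seed = 2)
  expect_identical(again$counts, out$counts)
})

test_that("subsampling preserves proportions in expectation", {
  counts <- rbind(s = c(30000L, 15000L, 5000L))
  colnames(counts) <- paste0("p", 1:3)
  tab <- phylotype_table(counts)
  props <- t(vapply(1:40, function(s) {
    out <- depth_filter_subsample(tab, seed = s)
    out$counts[1, ] / 20000
  }, numeric(3)))
  truth <- counts[1, ] / 50000
  se <- sqrt(truth * (1 - truth) / 20000 / 40)
  expect_true(all(abs(colMeans(props) - truth) < 3 * se + 1e-9))
})

test_that("analysis depth filter drops samples under 1000 reads", {
  counts <- rbind(a = c(999L, 0L), b = c(500L, 500L), c = c(4000L, 1000L))
  colnames(counts) <- c("p1", "p2")
  tab <- phylotype_table(counts)
  out <- analysis_depth_filter(tab)
  expect_setequal(rownames(out$counts), c("b", "c"))
  # identity on already-deep tables; empty in, empty out
  expect_identical(analysis_depth_filter(out)$counts, out$counts)
  empty <- phylotype_table(counts[0, , drop = FALSE])
  expect_equal(nrow(analysis_depth_filter(empty)$counts), 0L)
})

test_that("FASTQ round-trips through Biostrings", {
  sp <- spike_sequences(seed = 2)
  reads <- rbind(make_read("r1", 360, 35), make_read("r2", 350, 38,
                                                     seq = sp[1]))
  f <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, f)
  back <- read_fastq(f)
  expect_equal(back$sequence, reads$sequence)
  expect_equal(back$quality, reads$quality)
  expect_equal(back$id, reads$id)
})
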