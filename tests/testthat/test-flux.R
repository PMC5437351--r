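ann_simple <- genome_annotation(1, 850, 1000)

test_that("genome annotation partitions the genome without overlap", {
  iv <- ann_simple$intervals
  expect_equal(sum(iv$end - iv$start + 1), 1000)
  expect_equal(iv$kind, c("coding", "intergenic"))
  multi <- genome_annotation(c(10, 50, 40), c(30, 80, 60), 100)
  iv <- multi$intervals
  expect_true(all(iv$start[-1] == iv$end[-nrow(iv)] + 1))
  expect_error(genome_annotation(0, 10, 100), "outside")
})

test_that("indel tallies stratify by kind and region", {
  no_events <- data.frame(position = integer(0), kind = character(0),
                          length = integer(0))
  fs <- tally_indels(no_events, ann_simple)
  expect_true(all(fs$event_counts == 0))
  expect_true(all(fs$nucleotides == 0))

  events <- data.frame(
    position = c(10, 20, 900, 950, 100),
    kind = c("deletion", "insertion", "deletion", "insertion", "deletion"),
    length = c(35590, 5, 7, 3, 10))
  expect_warning(fs <- tally_indels(events, ann_simple), "boundary")
  expect_equal(fs$nucleotides["deletion", "coding"], 35600)
  expect_equal(fs$nucleotides["insertion", "coding"], 5)
  expect_equal(fs$nucleotides["deletion", "intergenic"], 7)
  expect_equal(fs$event_counts["insertion", "intergenic"], 1)
  # region totals sum to overall totals per kind
  expect_equal(sum(fs$nucleotides["deletion", ]),
               sum(events$length[events$kind == "deletion"]))

  oob <- data.frame(position = 2000, kind = "deletion", length = 5)
  expect_error(tally_indels(oob, ann_simple), "outside the genome")
})

test_that("events spanning a region boundary warn and follow their start", {
  ev <- data.frame(position = 845, kind = "deletion", length = 20)
  expect_warning(fs <- tally_indels(ev, ann_simple), "boundary")
  expect_equal(fs$nucleotides["deletion", "coding"], 20)
})

test_that("deletion rate arithmetic and scaling", {
  expect_equal(deletion_rate(100, 1e6, 100), 1e-6)
  expect_equal(deletion_rate(0, 1e6, 100), 0)
  expect_error(deletion_rate(10, 0, 10), "positive")
  # linear in deleted nt, inverse in generations
  base <- deletion_rate(500, 2e6, 1000)
  expect_equal(deletion_rate(1000, 2e6, 1000), 2 * base)
  expect_equal(deletion_rate(500, 2e6, 2000), base / 2)
})

test_that("per-year conversion and fold ratios match the printed bounds", {
  expect_equal(per_year_to_per_generation(2.9e-8, 50), 5.8e-10)
  expect_equal(per_year_to_per_generation(2.9e-8, 15), 1.933333e-9,
               tolerance = 1e-6)
  expect_equal(per_year_to_per_generation(0, 20), 0)

  expect_equal(rate_ratio(1.58e-6, 1.9e-9)$fold, 831)
  expect_equal(rate_ratio(1.28e-7, 1.9e-9)$fold, 67)
  expect_equal(rate_ratio(1e-9, 1e-9)$fold, 1)
})

test_that("event balance test reproduces printed binomial p-values", {
  expect_equal(test_event_balance(83, 41), 2e-4, tolerance = 0.05)
  expect_equal(test_event_balance(35, 15), 0.007, tolerance = 0.06)
  expect_equal(test_event_balance(10, 10), 1)
  expect_error(test_event_balance(0, 0), "at least one")
})

test_that("coding-vs-intergenic contingency test wires the right table", {
  ann <- genome_annotation(1, 500, 1000)
  ev <- data.frame(
    position = c(10, 20, 600, 700),
    kind = c("deletion", "insertion", "deletion", "insertion"),
    length = c(40, 10, 10, 40))
  fs <- tally_indels(ev, ann)
  res <- coding_vs_intergenic_test(fs)
  expect_equal(res$or_cmle, fisher_exact(40, 10, 10, 40)$or_cmle)

  # a uniform table estimates OR = 1
  ev2 <- data.frame(position = c(10, 20, 600, 700),
                    kind = c("deletion", "insertion", "deletion", "insertion"),
                    length = c(10, 10, 10, 10))
  expect_equal(coding_vs_intergenic_test(tally_indels(ev2, ann))$or_cmle, 1,
               tolerance = 1e-6)
})

test_that("simulated indel streams are conserved through the tally", {
  sim <- simulate_indels(genome_length = 1e5, coding_fraction = 0.8,
                         n_events = 500, p_deletion = 1, seed = 11)
  fs <- tally_indels(sim$events, sim$annotation)
  expect_equal(sum(fs$nucleotides["insertion", ]), 0)
  expect_equal(sum(fs$nucleotides["deletion", ]), sum(sim$events$length))
  expect_equal(sum(fs$event_counts), nrow(sim$events))

  big <- simulate_indels(genome_length = 1e5, coding_fraction = 0.8,
                         n_events = 10, p_deletion = 0.5,
                         big_deletion = c(1000, 35590), seed = 2)
  expect_true(any(big$events$kind == "deletion" &
                    big$events$length == 35590))

  # recovered deleted:inserted nucleotide ratio tracks the generating bias
  sim <- simulate_indels(genome_length = 1e6, coding_fraction = 0.9,
                         n_events = 4000, p_deletion = 0.8, seed = 13)
  fs <- tally_indels(sim$events, sim$annotation, generations = 100)
  frac_del_events <- sum(fs$event_counts["deletion", ]) / 4000
  expect_lt(abs(frac_del_events - 0.8), 3.3 * sqrt(0.8 * 0.2 / 4000))
  expect_equal(fs$deletion_rate,
               sum(fs$nucleotides["deletion", ]) / (1e6 * 100))
})
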