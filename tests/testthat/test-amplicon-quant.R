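# Read outcome calls, indel catalog, background subtraction, summaries.

serp <- local({
  cfg <- scenario_config("serpina1_correction", seed = 31)
  list(cfg = cfg, ed = build_edited_allele(cfg$amplicon, cfg$edit))
})

test_that("precise calls require both the edit and the PAM modification", {
  amp <- serp$cfg$amplicon; edit <- serp$cfg$edit
  # A-to-G installed but PAM left unmodified: not precise
  partial <- amp$sequence
  substr(partial, edit$ref_start + 1, edit$ref_start + 1) <- edit$alt
  oc <- call_read_outcome(partial, amp, edit, serp$ed)
  expect_identical(oc$call, "substitution_other")
  # both changes: precise
  oc2 <- call_read_outcome(serp$ed$sequence, amp, edit, serp$ed)
  expect_identical(oc2$call, "precise_edit")
  # unedited: wild type
  oc3 <- call_read_outcome(amp$sequence, amp, edit, serp$ed)
  expect_identical(oc3$call, "wild_type")
})

test_that("the 47-bp reporter-restoring deletion is precise with one 47-bp event", {
  set.seed(32)
  broken <- random_dna(260)   # reporter amplicon carrying the 47-bp disruption
  amp <- amplicon_spec("gfp_reporter_synthetic", broken, peg_nick = 100,
                       nick_sgrna_nick = 160)
  edit <- edit_spec("deletion", 100, 147, "", quant_window = c(95, 152))
  ed <- build_edited_allele(amp, edit)
  oc <- call_read_outcome(ed$sequence, amp, edit, ed)
  expect_identical(oc$call, "precise_edit")
  ev <- oc$events[[1]]
  del <- ev[ev$kind == "deletion", ]
  expect_equal(nrow(del), 1)
  expect_equal(del$length, 47)
})

test_that("reads not covering the window are ambiguous, never dropped", {
  amp <- serp$cfg$amplicon; edit <- serp$cfg$edit
  short <- substr(amp$sequence, 1, 60)  # ends before the window
  oc <- call_read_outcome(short, amp, edit, serp$ed, ref_free_ends = TRUE)
  expect_identical(oc$call, "ambiguous")
})

test_that("indel catalog counts distinct keys with read-fraction frequencies", {
  amp <- serp$cfg$amplicon; edit <- serp$cfg$edit
  del2 <- paste0(substr(amp$sequence, 1, 105), substr(amp$sequence, 108, 220))
  reads <- make_reads(c(rep(amp$sequence, 7), rep(del2, 3)))
  oc <- call_read_outcomes(reads, amp, edit, serp$ed)
  tab <- catalog_indels(oc)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$reads, 3L)
  expect_equal(tab$freq, 0.3)
  # zero-event run: empty table, total preserved
  oc0 <- call_read_outcomes(make_reads(rep(amp$sequence, 5)), amp, edit, serp$ed)
  tab0 <- catalog_indels(oc0)
  expect_equal(nrow(tab0), 0)
  expect_equal(attr(tab0, "total"), 5)
})

test_that("catalogued frequencies track generator truth", {
  cfg <- scenario_config("serpina1_correction", seed = 33, n_molecules = 4000,
                         q20_fraction = 0)
  mols <- simulate_molecules(cfg)
  sq <- amplify_and_sequence(mols, cfg)
  res <- run_amplicon(cfg$amplicon, cfg$edit, sq$r1, sq$r2)
  n <- res$summary$n_reads
  # indel calls are window-scoped: compare against indel-kind truth
  truth_frac <- mean(mols$category == "small_indel_sub" &
                       mols$event_kind != "substitution")
  se <- sqrt(truth_frac * (1 - truth_frac) / n)
  expect_lt(abs(res$summary$indel_rate - truth_frac), 3 * se + 0.005)
})

mk_tab <- function(df, total = 100L) {
  tab <- tibble::as_tibble(df)
  tab$reads <- as.integer(round(tab$freq * total))
  attr(tab, "total") <- total
  attr(tab, "amplicon_name") <- "amp"
  tab[, c("kind", "ref_pos", "length", "allele", "reads", "freq")]
}

test_that("background subtraction averages controls, floors at zero", {
  key <- list(kind = "deletion", ref_pos = 10L, length = 2L, allele = "AC")
  treat <- mk_tab(data.frame(key, freq = 0.050))
  ctls <- lapply(c(0.010, 0.020, 0.000), function(f)
    mk_tab(data.frame(key, freq = f)))
  net <- subtract_background(treat, ctls)
  expect_equal(net$net_freq, 0.040)
  # treatment equal to the control mean cancels exactly
  treat0 <- mk_tab(data.frame(key, freq = 0.010))
  expect_equal(subtract_background(treat0, ctls)$net_freq, 0)
  # control-only artifact: retained at net zero, never negative
  other <- mk_tab(data.frame(kind = "insertion", ref_pos = 50L, length = 1L,
                             allele = "T", freq = 0.02))
  net2 <- subtract_background(treat, c(ctls, list(other)))
  row <- net2[net2$kind == "insertion", ]
  expect_equal(row$net_freq, 0)
  # keys absent from all controls pass through unchanged
  lone <- mk_tab(data.frame(kind = "insertion", ref_pos = 7L, length = 3L,
                            allele = "AAA", freq = 0.015))
  net3 <- subtract_background(lone, ctls)
  expect_equal(net3$net_freq[net3$kind == "insertion"], 0.015)
})

test_that("subtraction of random tables never yields negative frequencies", {
  set.seed(34)
  for (i in 1:20) {
    keys <- data.frame(kind = sample(c("deletion", "insertion"), 6, TRUE),
                       ref_pos = sample(1:50, 6), length = sample(1:5, 6, TRUE),
                       allele = replicate(6, random_dna(2)))
    treat <- mk_tab(cbind(keys, freq = runif(6, 0, 0.1)))
    ctls <- lapply(1:3, function(j) mk_tab(cbind(keys, freq = runif(6, 0, 0.1))))
    net <- subtract_background(treat, ctls)
    expect_true(all(net$net_freq >= 0))
    expect_true(all(net$net_freq <= net$freq + 1e-12))
  }
})

test_that("subtraction refuses controls from a different amplicon", {
  key <- list(kind = "deletion", ref_pos = 10L, length = 2L, allele = "AC")
  treat <- mk_tab(data.frame(key, freq = 0.05))
  ctl <- mk_tab(data.frame(key, freq = 0.01))
  attr(ctl, "amplicon_name") <- "other"
  expect_error(subtract_background(treat, list(ctl)), "amplicon")
})

test_that("summary rates partition all passing reads", {
  amp <- serp$cfg$amplicon; edit <- serp$cfg$edit
  del2 <- paste0(substr(amp$sequence, 1, 105), substr(amp$sequence, 108, 220))
  reads <- make_reads(c(rep(amp$sequence, 50), rep(serp$ed$sequence, 30), rep(del2, 20)))
  oc <- call_read_outcomes(reads, amp, edit, serp$ed)
  s <- summarize_amplicon(oc)
  expect_equal(s$wild_type_rate, 0.5)
  expect_equal(s$precise_rate, 0.3)
  expect_equal(s$indel_rate, 0.2)
  expect_equal(s$precise_rate + s$indel_rate + s$wild_type_rate +
                 s$substitution_other_rate + s$ambiguous_rate, 1, tolerance = 1e-9)
  expect_error(summarize_amplicon(oc[0, ]), "no passing reads")
  # tidy/glance accessors
  td <- tidy(s)
  expect_equal(sum(td$rate), 1, tolerance = 1e-9)
  expect_equal(nrow(glance(s)), 1)
})

test_that("error-free precise molecules are always called precise", {
  for (seed in 1:60) {
    cfg <- scenario_config(c("serpina1_correction", "ctnnb1_s45del")[1 + seed %% 2],
                           seed = seed, n_molecules = 2,
                           mixture = c(precise_edit = 1), error_rate = 0,
                           q20_fraction = 0)
    mols <- simulate_molecules(cfg)
    ed <- build_edited_allele(cfg$amplicon, cfg$edit)
    oc <- call_read_outcomes(make_reads(mols$sequence), cfg$amplicon, cfg$edit, ed)
    expect_true(all(oc$call == "precise_edit"), info = paste("seed", seed))
  }
})

test_that("background subtraction never alters precise calls", {
  cfg <- scenario_config("serpina1_correction", seed = 35, n_molecules = 600,
                         q20_fraction = 0)
  mols <- simulate_molecules(cfg)
  sq <- amplify_and_sequence(mols, cfg)
  # same scenario seed so treatment and control share the same synthetic locus
  ctl_cfg <- scenario_config("serpina1_correction", seed = 35, n_molecules = 300,
                             mixture = c(wild_type = 1), q20_fraction = 0)
  ctl <- amplify_and_sequence(simulate_molecules(ctl_cfg), ctl_cfg)
  res <- run_amplicon(cfg$amplicon, cfg$edit, sq$r1, sq$r2,
                      controls = list(list(r1 = ctl$r1, r2 = ctl$r2)))
  res0 <- run_amplicon(cfg$amplicon, cfg$edit, sq$r1, sq$r2)
  expect_equal(res$summary$precise_rate, res0$summary$precise_rate)
  expect_true(!is.null(res$summary$net_indel_rate))
  expect_gte(res$summary$net_indel_rate, 0)
})
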