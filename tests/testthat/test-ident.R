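mk_db <- function(...) {
  seqs <- list(...)
  data.frame(id = paste0("ref", seq_along(seqs)),
             species = names(seqs),
             bases = unlist(seqs, use.names = FALSE),
             stringsAsFactors = FALSE)
}

test_that("pairwise identity: exact, substituted and nested sequences", {
  q <- random_dna(244, seed = 1)
  expect_equal(pairwise_identity(q, q), 1.0)
  m <- mutate_sequence(q, 5 / 244, seed = 2)   # exactly 5 substitutions
  expect_equal(pairwise_identity(q, m), 239 / 244, tolerance = 1e-9)
  # free end gaps: a query nested in a longer reference is a perfect match
  longref <- paste0(random_dna(90, seed = 3), q, random_dna(90, seed = 4))
  expect_equal(pairwise_identity(q, longref), 1.0)
  # symmetry
  expect_equal(pairwise_identity(m, q), pairwise_identity(q, m))
  expect_error(pairwise_identity("ACGT", q), "minimum length")
})

test_that("species assignment applies the inclusive 98% rule", {
  ref <- random_dna(250, seed = 10)
  other <- mutate_sequence(ref, 0.15, seed = 11)
  db <- mk_db(SpeciesA = ref, SpeciesB = other)

  # exact match -> assigned
  res <- identify_host(ref, db)
  expect_equal(res$status, "assigned")
  expect_equal(res$assigned_species, "SpeciesA")

  # 245/250 = 98.0% exactly: inclusive threshold assigns
  q98 <- mutate_sequence(ref, 5 / 250, seed = 12)
  expect_equal(pairwise_identity(q98, ref), 0.98, tolerance = 1e-9)
  expect_equal(identify_host(q98, db)$status, "assigned")

  # best hit below 98% (239/244 with a 244-nt query) -> unassigned
  ref244 <- random_dna(244, seed = 13)
  db244 <- mk_db(SpeciesA = ref244,
                 SpeciesB = mutate_sequence(ref244, 0.15, seed = 14))
  q_low <- mutate_sequence(ref244, 5 / 244, seed = 15)
  expect_lt(pairwise_identity(q_low, ref244), 0.98)
  expect_equal(identify_host(q_low, db244)$status, "unassigned")
})

test_that("two species tying above threshold give an ambiguous call", {
  ref <- random_dna(300, seed = 20)
  q <- mutate_sequence(ref, 3 / 300, seed = 21)
  db <- mk_db(SpeciesA = ref, SpeciesB = ref,   # same sequence, two species
              SpeciesC = mutate_sequence(ref, 0.2, seed = 22))
  expect_equal(identify_host(q, db)$status, "ambiguous")
  # duplicate references of the SAME species are not a tie
  db2 <- mk_db(SpeciesA = ref, SpeciesA2 = ref)
  db2$species <- c("SpeciesA", "SpeciesA")
  expect_equal(identify_host(q, db2)$status, "assigned")
})

test_that("threshold extremes behave as bounds", {
  ref <- random_dna(200, seed = 30)
  db <- mk_db(SpeciesA = ref,
              SpeciesB = mutate_sequence(ref, 0.3, seed = 31))
  far <- mutate_sequence(ref, 0.25, seed = 32)
  expect_equal(identify_host(far, db, threshold = 0)$status, "assigned")
  expect_equal(identify_host(far, db, threshold = 1)$status, "unassigned")
  expect_equal(identify_host(ref, db, threshold = 1)$status, "assigned")
  expect_error(identify_host(ref, db[0, ]), "empty")
})

test_that("external references resolve queries the primary db cannot", {
  anole <- random_dna(400, seed = 40)
  # primary db holds only a diverged lineage (~95%); external the local one
  primary <- mk_db(LizardA = mutate_sequence(anole, 0.05, seed = 41),
                   FrogB = mutate_sequence(anole, 0.3, seed = 42))
  external <- mk_db(LizardA = mutate_sequence(anole, 3 / 400, seed = 43))
  external$provenance <- "external-supplement"

  res <- identify_host(anole, primary)
  expect_equal(res$status, "unassigned")
  res2 <- resolve_external(res, anole, external)
  expect_equal(res2$status, "resolved_by_external_reference")
  expect_equal(res2$assigned_species, "LizardA")

  # below threshold everywhere: unchanged
  res3 <- resolve_external(res, anole,
                           mk_db(Other = mutate_sequence(anole, 0.1,
                                                         seed = 44)))
  expect_equal(res3$status, "unassigned")

  # assigned input violates the precondition
  ok <- identify_host(anole, external)
  expect_error(resolve_external(ok, anole, external), "unassigned")
})

test_that("hierarchical attempts stop at the first successful combination", {
  st <- make_study(n_samples = 1, seed = 50,
                   dp = degradation_params(c(BF1 = 0, BF2 = 0, BF3 = 0)))
  smp <- st$samples[[1]]

  # intact template: one attempt, shortest pair first
  out <- hierarchical_identify(smp, st$db)
  expect_equal(nrow(out$attempts), 1L)
  expect_equal(out$attempts$pair[1], "Mod_RepCOI_F+VertCOI_7216_R")
  expect_true(out$attempts$success[1])
  expect_equal(out$status, "assigned")
  expect_equal(out$identification$assigned_species, smp$true_host)

  # knock out the 244-pair reverse site (3' clamp of VertCOI_7216_R, which
  # maps to the leftmost sense bases of its site) -> succeeds on attempt 2
  tpl <- smp$fragments[1]
  ch <- strsplit(tpl, "", fixed = TRUE)[[1]]
  r2_site_start <- 25 + 221 + 1
  for (k in 0:2) ch[r2_site_start + k] <- setdiff(c("A", "C", "G", "T"),
                                                  ch[r2_site_start + k])[1]
  smp2 <- smp; smp2$fragments <- paste(ch, collapse = "")
  out2 <- hierarchical_identify(smp2, st$db)
  expect_equal(out2$attempts$success, c(FALSE, TRUE))
  expect_equal(out2$attempts$pair[2], "VertCOI_7194_F+Mod_RepCOI_R")
  expect_equal(out2$status, "assigned")

  # heavily fragmented template: three failed attempts, no amplification
  smp3 <- smp
  smp3$fragments <- degrade_template(tpl, lambda = 0.05, seed = 51)
  expect_true(max(nchar(smp3$fragments)) < 244)
  out3 <- hierarchical_identify(smp3, st$db)
  expect_equal(nrow(out3$attempts), 3L)
  expect_false(any(out3$attempts$success))
  expect_equal(out3$status, "no_amplification")
})

test_that("a complete synthetic study is identified perfectly when undegraded", {
  st <- make_study(n_samples = 30, seed = 60,
                   dp = degradation_params(c(BF1 = 0, BF2 = 0, BF3 = 0)))
  outs <- lapply(st$samples, hierarchical_identify, db = st$db)
  hosts <- vapply(outs, function(o) o$identification$assigned_species, "")
  truth <- vapply(st$samples, `[[`, "", "true_host")
  expect_equal(hosts, truth)
})

test_that("withheld species are recovered through the external path", {
  st <- make_study(n_samples = 40, seed = 61,
                   dp = degradation_params(c(BF1 = 0, BF2 = 0, BF3 = 0)),
                   withhold_hosts = "Host_species_03")
  idx <- vapply(st$samples, `[[`, "", "true_host") == "Host_species_03"
  expect_true(any(idx))
  outs <- lapply(st$samples[idx], hierarchical_identify, db = st$db,
                 external_db = st$external_db)
  expect_true(all(vapply(outs, `[[`, "", "status") ==
                    "resolved_by_external_reference"))
  expect_true(all(vapply(outs, function(o)
    o$identification$assigned_species, "") == "Host_species_03"))
})

test_that("host tabulation counts and conserves column sums", {
  st <- make_study(n_samples = 25, seed = 62,
                   dp = degradation_params(c(BF1 = 0, BF2 = 0, BF3 = 0)))
  outs <- lapply(st$samples, hierarchical_identify, db = st$db)
  tab <- tabulate_hosts(outs)
  mosq <- vapply(outs, `[[`, "", "mosquito_species")
  expect_equal(colSums(tab), c(table(mosq)))
  expect_equal(sum(tab), length(outs))
  # invariant under permutation of input order
  tab2 <- tabulate_hosts(rev(outs))
  expect_equal(tab2[rownames(tab), colnames(tab)], tab)
  # duplicates rejected; empty input tolerated
  expect_error(tabulate_hosts(c(outs, outs[1])), "duplicate")
  expect_equal(dim(tabulate_hosts(list())), c(0L, 0L))
})

test_that("no-amplification samples appear as their own row", {
  st <- make_study(n_samples = 3, seed = 63,
                   dp = degradation_params(c(BF1 = 0, BF2 = 0, BF3 = 0)))
  outs <- lapply(st$samples, hierarchical_identify, db = st$db)
  outs[[2]]$status <- "no_amplification"
  outs[[2]]$identification <- NULL
  tab <- tabulate_hosts(outs)
  expect_true("No amplification" %in% rownames(tab))
  expect_equal(sum(tab["No amplification", ]), 1)
})
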