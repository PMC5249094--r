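default_ped <- cohort_pedigree(cohort_design())
default_samples <- as.data.frame(default_ped)$id

test_that("depth filter keeps fully covered records and drops boundary failures", {
  vs <- random_variant_set(5, default_samples, p_indel = 0)
  vs$dp[] <- 30L
  expect_equal(nrow(depth_filter(vs, default_ped)$sites), 5)
  vs$dp[2, "affected_1"] <- 9L # boundary: just below the cut
  vs$dp[4, "affected_2"] <- 10L # boundary: exactly at the cut
  kept <- depth_filter(vs, default_ped)
  expect_equal(site_key(kept), site_key(vs[c(1, 3, 4, 5)]))
  # control depth is exempt under the default core scope but not under "all"
  vs$dp[1, "control_3"] <- 0L
  expect_true(site_key(vs)[1] %in% site_key(depth_filter(vs, default_ped)))
  expect_false(
    site_key(vs)[1] %in%
      site_key(depth_filter(vs, default_ped, filter_criteria(depth_scope = "all")))
  )
})

test_that("depth and segregation filters agree with per-record brute force", {
  set.seed(77)
  vs <- random_variant_set(200, default_samples)
  roles <- ped_roles(default_ped)
  # depth oracle
  dkeep <- vapply(seq_len(nrow(vs$sites)), function(i) {
    d <- vs$dp[i, c(roles$affected, roles$parents)]
    !any(is.na(d)) && all(d >= 10)
  }, logical(1))
  expect_equal(site_key(depth_filter(vs, default_ped)), site_key(vs[dkeep]))
  # segregation oracle
  skeep <- vapply(seq_len(nrow(vs$sites)), function(i) {
    all(vs$gt[i, roles$affected] == "hom_alt") &&
      all(vs$gt[i, roles$parents] %in% c("het", "hemi")) &&
      !any(vs$gt[i, roles$controls] == "hom_alt")
  }, logical(1))
  expect_equal(
    site_key(segregation_filter_snv(vs, default_ped)),
    site_key(vs[skeep])
  )
})

test_that("missing genotypes fail affected/parent requirements but not control exclusion", {
  vs <- random_variant_set(3, default_samples, p_indel = 0)
  roles <- ped_roles(default_ped)
  vs$gt[, roles$affected] <- "hom_alt"
  vs$gt[, roles$parents] <- "het"
  vs$gt[, roles$controls] <- "hom_ref"
  vs$gt[1, "affected_1"] <- "missing"
  vs$gt[2, "control_1"] <- "missing"
  kept <- segregation_filter_snv(vs, default_ped)
  expect_equal(site_key(kept), site_key(vs[2:3]))
})

test_that("a hom-alt record with one het affected is removed", {
  vs <- random_variant_set(1, default_samples, p_indel = 0)
  roles <- ped_roles(default_ped)
  vs$gt[, roles$affected] <- "hom_alt"
  vs$gt[, roles$parents] <- "het"
  vs$gt[, roles$controls] <- "hom_ref"
  vs$gt[1, "affected_2"] <- "het"
  expect_equal(nrow(segregation_filter_snv(vs, default_ped)$sites), 0)
})

test_that("empty input flows through both funnels as all-zero reports", {
  vs <- random_variant_set(1, default_samples)[integer(0)]
  ref <- make_known_reference()
  snv <- run_snv_funnel(vs, default_ped, ref$genes, ref)
  indel <- run_indel_funnel(vs, default_ped, ref$genes)
  expect_true(all(snv$steps$count == 0))
  expect_true(all(indel$steps$count == 0))
})

test_that("funnel step order mirrors the published SNV and indel branches", {
  expect_equal(
    trioscreen:::SNV_FUNNEL_STEPS,
    c(
      "total", "coverage_ge_min_depth", "gene_coding", "exon_coding",
      "affected_hom_parent_het", "control_not_hom_alt", "missense"
    )
  )
  expect_equal(
    trioscreen:::INDEL_FUNNEL_STEPS,
    c(
      "total", "coverage_ge_min_depth", "carried_by_all_affected_and_parents",
      "affected_hom_alt", "parent_het", "control_not_hom_alt", "exon_coding"
    )
  )
})

test_that("planted causal variant survives the funnel with error-free genotyping", {
  sim <- simulate_cohort(cohort_design(seed = 42, n_background_variants = 500),
    dir = withr::local_tempdir()
  )
  vs <- read_vcf(sim$vcf)
  ped <- read_ped(sim$ped)
  rep <- run_snv_funnel(vs, ped, sim$reference$genes, sim$reference)
  causal_key <- with(
    sim$truth$sites[sim$truth$causal, ],
    paste(chrom, pos, ref, alt, sep = ":")
  )
  expect_true(causal_key %in% site_key(rep$survivors))
  # survivor set equals the brute-force predicate conjunction
  keep <- oracle_snv_survivors(vs, ped, sim$reference$genes, sim$reference)
  expect_setequal(site_key(rep$survivors), site_key(vs[keep]))
})

test_that("funnels agree with brute force and stay monotone on random cohorts", {
  set.seed(555)
  ref <- make_known_reference()
  for (rep_i in 1:25) {
    vs <- random_variant_set(40, default_samples,
      p_indel = 0.4, max_pos = 100,
      reference = ref
    )
    snv <- run_snv_funnel(vs, default_ped, ref$genes, ref)
    ind <- run_indel_funnel(vs, default_ped, ref$genes)
    expect_true(all(diff(snv$steps$count) <= 0))
    expect_true(all(diff(ind$steps$count) <= 0))
    expect_setequal(
      site_key(snv$survivors),
      site_key(vs[oracle_snv_survivors(vs, default_ped, ref$genes, ref)])
    )
    expect_setequal(
      site_key(ind$survivors),
      site_key(vs[oracle_indel_survivors(vs, default_ped, ref$genes)])
    )
  }
})

test_that("filters are idempotent and the final set is order-free", {
  set.seed(99)
  vs <- random_variant_set(150, default_samples)
  once_d <- depth_filter(vs, default_ped)
  expect_equal(site_key(depth_filter(once_d, default_ped)), site_key(once_d))
  once_s <- segregation_filter_snv(vs, default_ped)
  expect_equal(
    site_key(segregation_filter_snv(once_s, default_ped)),
    site_key(once_s)
  )
  # both orders of depth/segregation give the same final set
  a <- segregation_filter_snv(depth_filter(vs, default_ped), default_ped)
  b <- depth_filter(segregation_filter_snv(vs, default_ped), default_ped)
  expect_setequal(site_key(a), site_key(b))
})

test_that("pedigree samples missing from the VCF raise a configuration error", {
  vs <- random_variant_set(3, c("affected_1", "control_1"))
  expect_error(depth_filter(vs, default_ped), "absent from the VCF")
})

test_that("a perfectly segregating intergenic indel is removed at the exon step", {
  ref <- make_known_reference()
  roles <- ped_roles(default_ped)
  vs <- random_variant_set(1, default_samples, p_indel = 0, max_pos = 100)
  vs$sites$pos <- 90L # intergenic on the known reference
  vs$sites$ref <- "AT"
  vs$sites$alt <- "A"
  vs <- variant_set(vs$sites[, c("chrom", "pos", "ref", "alt")], vs$gt, vs$dp)
  vs$gt[, roles$affected] <- "hom_alt"
  vs$gt[, roles$parents] <- "het"
  vs$gt[, roles$controls] <- "hom_ref"
  vs$dp[] <- 30L
  rep <- run_indel_funnel(vs, default_ped, ref$genes)
  expect_equal(rep$steps$count, c(1L, 1L, 1L, 1L, 1L, 1L, 0L))
})

test_that("funnel report TSV has step name and count per line", {
  ref <- make_known_reference()
  set.seed(12)
  vs <- random_variant_set(10, default_samples, max_pos = 100, reference = ref)
  rep <- run_snv_funnel(vs, default_ped, ref$genes, ref)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_funnel_report(rep, path)
  lines <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(lines$V1, rep$steps$step)
  expect_equal(lines$V2, rep$steps$count)
})
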