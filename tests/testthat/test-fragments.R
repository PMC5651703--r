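test_that("SAM fixture yields exactly one retained fragment", {
  panel <- sam_fixture_panel()
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam_fixture(path)
  frags <- load_fragments(path, panel)
  expect_equal(n_distinct(frags$fragment_id), 1L)
  expect_equal(frags$fragment_id, "p1")
  expect_equal(frags$length, 465L)
  expect_equal(frags$snp_id, "rs1")
  expect_equal(frags$base, "G")
  stats <- attr(frags, "starr_filter_stats")
  expect_equal(unname(stats["dropped_length"]), 1L)  # the 700-bp pair
  sam_stats <- attr(read_sam_fragments(path, panel), "starr_sam_stats")
  expect_equal(unname(sam_stats["excluded"]), 1L)  # the unpaired read
})

test_that("length and SNP-coverage filters drop boundary fragments", {
  panel <- sam_fixture_panel()
  mk <- function(len, start, snp = TRUE) {
    tibble(fragment_id = "f1", library = "input_1", chrom = "chr1",
           start = start, end = start + len, length = len,
           snp_id = if (snp) "rs1" else NA_character_,
           base = if (snp) "A" else NA_character_,
           qual = if (snp) 40L else NA_integer_)
  }
  # 399 bp covering a SNP: excluded by length
  expect_equal(nrow(load_fragments(mk(399L, 1000L), panel)), 0L)
  # boundary lengths 400 and 600 retained
  expect_equal(nrow(load_fragments(mk(400L, 1000L), panel)), 1L)
  expect_equal(nrow(load_fragments(mk(600L, 1000L), panel)), 1L)
  # 500 bp covering no panel SNP: excluded
  expect_equal(nrow(load_fragments(mk(500L, 5000L, snp = FALSE), panel)), 0L)
})

test_that("low-quality and mate-discordant bases become unknown", {
  panel <- sam_fixture_panel()
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam_fixture(path, snp_qual = "#")  # phred 2 < 20
  frags <- load_fragments(path, panel)
  expect_true(is.na(frags$base))
  mats <- count_matrices(frags, panel, libraries = "input_1")
  row <- filter(mats$allele_counts, snp_id == "rs1")
  expect_equal(row$unknown_count, 1L)
  expect_equal(row$ref_count + row$alt_count, 0L)
  # region count keeps the fragment despite the unknown allele
  expect_equal(filter(mats$counts, snp_id == "rs1")$input_1, 1L)

  # overlapping mates disagreeing at the SNP -> unknown
  path2 <- withr::local_tempfile(fileext = ".sam")
  s1 <- strrep("A", 100); substr(s1, 50, 50) <- "G"
  s2 <- strrep("A", 100)  # mate says A at same position
  lines <- c("@SQ\tSN:chr1\tLN:100000",
             sprintf("d1\t99\tchr1\t1001\t60\t100M\t=\t1001\t465\t%s\t%s",
                     s1, strrep("I", 100)),
             sprintf("d1\t147\tchr1\t1001\t60\t100M\t=\t1001\t-465\t%s\t%s",
                     s2, strrep("I", 100)))
  writeLines(lines, path2)
  frags2 <- read_sam_fragments(path2, panel)
  expect_true(is.na(frags2$base[frags2$snp_id == "rs1"]))
})

test_that("malformed SAM lines are skipped with a warning and counted", {
  panel <- sam_fixture_panel()
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam_fixture(path, extra_lines = "broken\tline\tonly")
  expect_warning(frags <- read_sam_fragments(path, panel), "malformed")
  expect_equal(unname(attr(frags, "starr_sam_stats")["malformed"]), 1L)
})

test_that("counting follows the one-count-per-covered-region rule", {
  panel <- tibble(chrom = "chr1", pos = c(100L, 300L), snp_id = c("A", "B"),
                  ref = c("A", "C"), alt = c("G", "T"), maf = c(0.1, 0.2))
  frag <- tibble(fragment_id = "f1", library = "input_1", chrom = "chr1",
                 start = 50L, end = 500L, length = 450L,
                 snp_id = c("A", "B"), base = c("A", "T"), qual = 40L)
  mats <- count_matrices(frag, panel, libraries = "input_1")
  expect_equal(mats$counts$input_1, c(1L, 1L))
  ac <- mats$allele_counts
  expect_equal(ac$ref_count[ac$snp_id == "A"], 1L)
  expect_equal(ac$alt_count[ac$snp_id == "B"], 1L)
  # a base matching neither allele is tracked separately
  frag$base <- c("T", "T")
  ac2 <- count_matrices(frag, panel, libraries = "input_1")$allele_counts
  expect_equal(ac2$other_count[ac2$snp_id == "A"], 1L)
})

test_that("zero fragments give an all-zero matrix over the full panel", {
  panel <- sam_fixture_panel()
  empty <- tibble(fragment_id = character(), library = character(),
                  chrom = character(), start = integer(), end = integer(),
                  length = integer(), snp_id = character(),
                  base = character(), qual = integer())
  mats <- count_matrices(empty, panel)
  expect_equal(nrow(mats$counts), 2L)
  expect_true(all(as.matrix(mats$counts[, -1]) == 0L))
})

test_that("counting is order-independent and errors on unknown SNPs", {
  ds <- simulate_dataset(tiny_config(seed = 4), emit_fragments = TRUE)
  kept <- load_fragments(ds$fragments, ds$panel)
  m1 <- count_matrices(kept, ds$panel)
  set.seed(1)
  shuffled <- kept[sample.int(nrow(kept)), ]
  m2 <- count_matrices(shuffled, ds$panel)
  expect_equal(m1$counts, m2$counts)
  expect_equal(m1$allele_counts, m2$allele_counts)

  rogue <- kept
  rogue$snp_id[1] <- "not_in_panel"
  expect_error(count_matrices(rogue, ds$panel), "absent from the panel")
})

test_that("generator fragments round-trip to the generator's own tallies", {
  ds <- simulate_dataset(tiny_config(seed = 6), emit_fragments = TRUE)
  kept <- load_fragments(ds$fragments, ds$panel)
  mats <- count_matrices(kept, ds$panel)
  expect_equal(as.data.frame(mats$counts),
               as.data.frame(ds$counts[, names(mats$counts)]))
  a1 <- arrange(mats$allele_counts, snp_id, library) |>
    select(snp_id, library, ref_count, alt_count)
  a2 <- arrange(ds$allele_counts, snp_id, library) |>
    select(snp_id, library, ref_count, alt_count)
  expect_equal(as.data.frame(a1), as.data.frame(a2))
})

test_that("synthetic SAM emission round-trips through the SAM reader", {
  cfg <- sim_config(n_tag_snps = 4, linked_per_tag = 1,
                    fragments_per_region = 8, seed = 11)
  ds <- simulate_dataset(cfg, emit_fragments = TRUE, emit_genome = TRUE)
  frag_in <- filter(ds$fragments, library == "input_1")
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(frag_in, ds$panel, path, genome = ds$genome)
  back <- load_fragments(path, ds$panel, library = "input_1")
  mats <- count_matrices(back, ds$panel, libraries = "input_1")
  truth_tally <- frag_in |>
    count(snp_id) |>
    right_join(tibble(snp_id = ds$panel$snp_id), by = "snp_id") |>
    mutate(n = tidyr::replace_na(n, 0L)) |>
    arrange(match(snp_id, ds$panel$snp_id))
  expect_equal(mats$counts$input_1, truth_tally$n)
  # alleles survive the sequence round trip
  ac <- mats$allele_counts
  orig <- frag_in |>
    left_join(select(ds$panel, snp_id, ref, alt), by = "snp_id") |>
    mutate(allele = ifelse(base == ref, "ref", "alt")) |>
    count(snp_id, allele) |>
    tidyr::pivot_wider(names_from = allele, values_from = n, values_fill = 0L)
  j <- inner_join(ac, orig, by = "snp_id")
  if (!"ref" %in% names(j)) j$ref <- 0L
  if (!"alt" %in% names(j)) j$alt <- 0L
  expect_equal(j$ref_count, j$ref)
  expect_equal(j$alt_count, j$alt)
})
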