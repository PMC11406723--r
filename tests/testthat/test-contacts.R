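test_that("pairs files parse, validate, and honor the error policy", {
  g <- genome_spec(c("chr1", "chr2"), c(1e7, 5e6))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "c1\tchr1\t1500000\tchr1\t2400000",
    "c1\tchr1\t500\tchr2\t900",
    "c2\tchr1\t1\tchr1\t10000000\t4",
    "c1\tchrZ\t100\tchr1\t200",        # unknown chromosome
    "c1\tchr1\t99999999\tchr1\t5"      # beyond chromosome length
  ), f)
  expect_warning(p <- read_pairs(f, g), "2 malformed")
  expect_equal(nrow(p), 3L)
  expect_equal(p$pos_a[1], 1500000)
  expect_equal(p$count, c(1, 1, 4))
  # inter-chromosomal record survives parsing (dropped later by binning)
  expect_true(p$chrom_a[2] != p$chrom_b[2])
  expect_error(read_pairs(f, g, on_error = "abort"), "malformed")

  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_equal(nrow(read_pairs(empty, g)), 0L)
})

test_that("binning maps positions to 0-based bins and accumulates symmetrically", {
  g <- genome_spec("chr1", 1e7)           # L = 10 Mb, R = 1 Mb
  expect_equal(unname(n_bins(g)), 10L)
  # three identical intra-chromosomal pairs at bins (2, 5)
  pairs <- data.frame(
    cell_id = "c1",
    chrom_a = "chr1", pos_a = c(2.5e6, 2.5e6, 2.5e6, 1.5e6),
    chrom_b = "chr1", pos_b = c(5.5e6, 5.5e6, 5.5e6, 1.2e6),
    count = 1
  )
  cells <- bin_pairs(pairs, g)
  A <- as.matrix(cells[["c1"]]$matrices[["chr1"]])
  expect_equal(A[3, 6], 3)                 # bin 2, 5 (0-based) -> [3, 6]
  expect_equal(A[6, 3], 3)
  expect_equal(A[2, 2], 1)                 # same-bin pair counted once
  expect_true(isSymmetric(A))
  # bin index rule: floor((pos - 1) / R)
  expect_equal(floor((1500000 - 1) / 1e6), 1)
})

test_that("inter-chromosomal pairs are discarded and every cell covers the genome", {
  g <- genome_spec(c("chr1", "chr2"), c(3e6, 3e6))
  pairs <- data.frame(
    cell_id = c("c1", "c1", "c2"),
    chrom_a = c("chr1", "chr1", "chr2"),
    pos_a = c(1e6, 1e6, 1e6),
    chrom_b = c("chr2", "chr1", "chr2"),
    pos_b = c(1e6, 2e6, 2e6),
    count = 1
  )
  cells <- bin_pairs(pairs, g)
  expect_named(cells, c("c1", "c2"))
  expect_named(cells[["c1"]]$matrices, c("chr1", "chr2"))
  expect_equal(total_contacts(cells[["c1"]]), 1)  # inter-chrom pair dropped
  expect_equal(sum(as.matrix(cells[["c2"]]$matrices[["chr1"]])), 0)
})

test_that("total_contacts equals an independent re-summation of the pair list", {
  g <- genome_spec("chr1", 2e7)
  set.seed(42)
  n <- 200
  pairs <- data.frame(
    cell_id = "c1",
    chrom_a = "chr1", pos_a = sample.int(2e7, n),
    chrom_b = "chr1", pos_b = sample.int(2e7, n),
    count = sample(1:3, n, replace = TRUE)
  )
  cells <- bin_pairs(pairs, g)
  expect_equal(total_contacts(cells[["c1"]]), sum(pairs$count))

  zero <- toy_cell(g, list())
  expect_equal(total_contacts(zero), 0)
  one <- toy_cell(g, list(chr1 = list(i = 2L, j = 5L, x = 3)))
  expect_equal(total_contacts(one), 3)
})

test_that("QC applies the depth threshold and the empty-chromosome rule", {
  g <- genome_spec(c("chr1", "chr2"), c(1e7, 1e7))
  low <- toy_cell(g, list(chr1 = list(i = 0L, j = 1L, x = 4998),
                          chr2 = list(i = 0L, j = 1L, x = 1)))
  expect_false(as.logical(passes_qc(low)))
  expect_true("LOW_DEPTH" %in% attr(passes_qc(low), "reasons"))

  exact <- toy_cell(g, list(chr1 = list(i = 0L, j = 1L, x = 4999),
                            chr2 = list(i = 0L, j = 1L, x = 1)))
  expect_true(as.logical(passes_qc(exact)))   # exactly 5000 passes

  deep_empty <- toy_cell(g, list(chr1 = list(i = 0L, j = 1L, x = 100000)))
  v <- passes_qc(deep_empty)
  expect_false(as.logical(v))
  expect_equal(attr(v, "reasons"), "EMPTY_CHROM")
})

test_that("filter_cells partitions its input exactly, preserving order", {
  expect_equal(filter_cells(list()),
               list(kept = list(), removed = list(), reasons = list()))
  g <- genome_spec("chr1", 1e7)
  set.seed(7)
  depths <- sample(3000:7000, 40)
  cells <- lapply(seq_along(depths), function(i) {
    toy_cell(g, list(chr1 = list(i = 0L, j = 3L, x = depths[i])),
             cell_id = paste0("c", i))
  })
  res <- filter_cells(cells, min_contacts = 5000)
  expect_equal(length(res$kept), sum(depths >= 5000))
  expect_equal(length(res$kept) + length(res$removed), length(cells))
  all_ids <- vapply(cells, function(c) c$cell_id, character(1))
  out_ids <- vapply(c(res$kept, res$removed), function(c) c$cell_id, character(1))
  expect_setequal(out_ids, all_ids)
  kept_ids <- vapply(res$kept, function(c) c$cell_id, character(1))
  expect_equal(kept_ids, all_ids[depths >= 5000])  # order preserved
})

test_that("the text contact container round-trips matrices and genome", {
  g <- genome_spec(c("chr1", "chr2"), c(5e6, 3e6))
  set.seed(11)
  cells <- lapply(1:3, function(i) {
    toy_cell(g, list(chr1 = list(i = c(0L, 1L), j = c(2L, 1L), x = c(2, 5)),
                     chr2 = list(i = 0L, j = 0L, x = i)),
             cell_id = paste0("c", i))
  })
  names(cells) <- paste0("c", 1:3)
  dir <- withr::local_tempdir()
  save_contacts(cells, g, dir)
  back <- load_contacts(dir)
  expect_equal(back$genome$chrom_names, g$chrom_names)
  expect_equal(names(back$cells), names(cells))
  for (cid in names(cells)) {
    for (ch in g$chrom_names) {
      expect_equal(as.matrix(back$cells[[cid]]$matrices[[ch]]),
                   as.matrix(cells[[cid]]$matrices[[ch]]))
    }
  }
})

test_that("generated pairs files round-trip through read_pairs and bin_pairs", {
  p <- sim_params(n_types = 2L, cells_per_type = c(3L, 3L),
                  genome = toy_genome(2L, 20L), depth_mean = 6000, seed = 5L)
  d <- generate_dataset(p, withr::local_tempdir())
  genome <- read_chrom_sizes(d$sizes)
  cells <- bin_pairs(read_pairs(d$pairs, genome), genome)
  expect_equal(names(cells), names(d$cells))
  for (cid in names(cells)) {
    for (ch in genome$chrom_names) {
      expect_equal(as.matrix(cells[[cid]]$matrices[[ch]]),
                   as.matrix(d$cells[[cid]]$matrices[[ch]]))
    }
  }
})
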