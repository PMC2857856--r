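test_that("probe table round-trips through the interchange format", {
  arrays <- tiny_arrayset(n_sets = 2, npp = 3, K = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_probe_table(arrays, path)
  back <- read_probe_table(path)
  expect_equal(dim(back$signals), c(6L, 3L))
  expect_equal(back$signals, arrays$signals, tolerance = 1e-6)
  expect_equal(back$annotation$sequence, arrays$annotation$sequence)
  expect_equal(back$annotation$dinuc, arrays$annotation$dinuc,
               ignore_attr = TRUE)
})

test_that("malformed tables are rejected with informative errors", {
  arrays <- tiny_arrayset()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_probe_table(arrays, path)

  tab <- readr::read_tsv(path, show_col_types = FALSE)
  tab$a2[3] <- 0
  bad <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tab, bad)
  expect_error(read_probe_table(bad), "probe row 3, array column 2")

  tab2 <- readr::read_tsv(path, show_col_types = FALSE)
  tab2$sequence <- NULL
  bad2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tab2, bad2)
  expect_error(read_probe_table(bad2), "sequence")

  expect_error(read_probe_table("no/such/file.tsv"), "not found")
})

test_that("a probe at the probe-set 3' end has all-zero dinucleotide counts", {
  ann <- tibble::tibble(
    probe_id = "p1", probeset_id = "s1",
    sequence = strrep("ACGTA", 5), x = 0L, y = 0L, dist3 = 0L)
  out <- probe_annotation(ann)
  expect_equal(unname(out$dinuc[1, ]), rep(0L, 16))
})

test_that("dinucleotide reconstruction matches a brute-force transcript scan", {
  # overlapping probes fully cover the transcript, so the reconstructed
  # counts must equal the true window counts
  withr::with_seed(11, {
    for (rep_i in 1:25) {
      npp <- 8
      gap <- 15  # < 25: consecutive probes overlap
      tr_len <- (npp - 1) * gap + 25
      codes <- sample(1:4, tr_len, replace = TRUE)
      starts <- 1 + (seq_len(npp) - 1) * gap
      centres <- starts + 12
      end3 <- max(centres)
      ann <- tibble::tibble(
        probe_id = sprintf("p%d", seq_len(npp)), probeset_id = "s1",
        sequence = vapply(starts, function(s) {
          paste(c("A", "C", "G", "T")[codes[s:(s + 24)]], collapse = "")
        }, character(1)),
        x = seq_len(npp) - 1L, y = 0L, dist3 = end3 - centres)
      got <- dinuc_counts_from_layout(ann)
      for (j in seq_len(npp)) {
        expect_equal(unname(got[j, ]),
                     brute_window_counts(codes, centres[j], end3))
      }
    }
  })
})

test_that("partially covered windows never overcount", {
  arrays <- tiny_arrayset(n_sets = 4, npp = 4)
  ann <- arrays$annotation
  counts <- dinuc_counts_from_layout(ann)
  expect_true(all(rowSums(counts) <= ann$dist3))
})

test_that("expression tables round-trip and QC drops are reported", {
  m <- matrix(rnorm(6), 2, 3,
              dimnames = list(c("s01", "s02"), c("a1", "a2", "a3")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(m, path)
  expect_identical(length(readLines(path)), 3L)  # header + 2 probe sets
  expect_equal(read_expression_table(path), m, tolerance = 1e-6)

  fake <- structure(list(expression = m,
                         removed_probesets = tibble::tibble(
                           probeset_id = "s99", reason = "all probes outlying")),
                    class = "rdn_expression")
  expect_message(write_expression_table(fake, path), "removed by QC")
  expect_false("s99" %in% rownames(read_expression_table(path)))
})

test_that("arrayset construction validates geometry and positivity", {
  arrays <- tiny_arrayset()
  ann <- arrays$annotation
  sig <- arrays$signals
  expect_error(rdn_arrayset(ann, sig[-1, ]), "match")
  sig2 <- sig; sig2[2, 1] <- -5
  expect_error(rdn_arrayset(ann, sig2), "probe row 2, array column 1")
  ann2 <- ann; ann2$x[2] <- ann2$x[1]; ann2$y[2] <- ann2$y[1]
  expect_error(probe_annotation(as.data.frame(ann2)[names(ann2) != "dinuc"]),
               "unique")
})
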