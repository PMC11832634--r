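test_that("Sparky rows map to peaks with shifts and labels", {
  f <- withr::local_tempfile(lines = c(
    "      Assignment       w1      w2",
    "",
    "      T212N-H       118.21    8.43",
    "        G45N-H      108.90    8.35",
    "          ?-?       120.00    8.10"))
  pl <- read_sparky_list(f, experiment = "HSQC", temperature = 5,
                         dims = c("N", "HN"))
  expect_s3_class(pl, "peak_list")
  expect_equal(nrow(pl), 3)
  expect_equal(pl$N, c(118.21, 108.90, 120.00))
  expect_equal(pl$HN, c(8.43, 8.35, 8.10))
  expect_equal(pl$label[1], "T212N-H")
  expect_equal(attr(pl, "temperature"), 5)
  # unassigned-peak convention
  parsed <- parse_assignment_label(pl$label[3])
  expect_true(is.na(parsed$res_type))
  expect_true(is.na(parsed$res_num))
})

test_that("empty files and malformed rows are handled as specified", {
  f <- withr::local_tempfile(lines = character(0))
  expect_warning(pl <- read_sparky_list(f, dims = c("N", "HN")), "empty")
  expect_equal(nrow(pl), 0)

  g <- withr::local_tempfile(lines = "T212N-H 118.21 eight")
  expect_error(read_sparky_list(g, dims = c("N", "HN")), "line 1")
  h <- withr::local_tempfile(lines = "T212N-H 118.21")
  expect_error(read_sparky_list(h, dims = c("N", "HN")), "columns")
})

test_that("write/read round trip preserves shifts and labels", {
  pl <- peak_list(cbind(c(118.212, 120.004), c(8.432, 8.101)),
                  dims = c("N", "HN"),
                  labels = c("T212N-H", "?-?"),
                  experiment = "HSQC", temperature = 10)
  f <- withr::local_tempfile()
  write_sparky_list(pl, f, digits = 3)
  back <- read_sparky_list(f, experiment = "HSQC", temperature = 10,
                           dims = c("N", "HN"))
  expect_equal(back$N, round(pl$N, 3))
  expect_equal(back$HN, round(pl$HN, 3))
  expect_identical(back$label, pl$label)
})

test_that("assignment labels parse per the Sparky convention", {
  p <- parse_assignment_label("T212N-H")
  expect_equal(p$res_type, "T")
  expect_equal(p$res_num, 212L)
  expect_equal(p$atoms, c("N", "H"))

  p <- parse_assignment_label("G45N-HN")
  expect_equal(p$res_type, "G")
  expect_equal(p$res_num, 45L)
  expect_equal(p$atoms, c("N", "HN"))

  p <- parse_assignment_label("S3N-CA-H")
  expect_equal(p$atoms, c("N", "CA", "H"))

  p <- parse_assignment_label("?-?")
  expect_true(is.na(p$res_type) && is.na(p$res_num))
})

test_that("label parsing is total: arbitrary strings never error", {
  set.seed(42)
  junk <- c("", "---", "123", "N-?", "@#!", "A-1-2-3-",
            vapply(1:50, function(i)
              paste(sample(c(LETTERS, letters, 0:9, "-", "?", "'"),
                           sample(1:12, 1), replace = TRUE),
                    collapse = ""), character(1)))
  for (s in junk)
    expect_no_error(suppressWarnings(parse_assignment_label(s)))
})

test_that("FASTA reading enforces a single clean record", {
  f <- withr::local_tempfile(lines = c(">x", "GASP"))
  expect_equal(read_fasta(f), c("G", "A", "S", "P"))

  g <- withr::local_tempfile(lines = c(">x", "GASP", ">y", "AA"))
  expect_error(read_fasta(g), "one FASTA record")

  h <- withr::local_tempfile(lines = c(">x", "gaSP"))
  expect_warning(s <- read_fasta(h), "upcased")
  expect_equal(s, c("G", "A", "S", "P"))

  i <- withr::local_tempfile(lines = c(">x", "GABZ"))
  expect_error(read_fasta(i), "position")
})

test_that("statistics tables are validated", {
  f <- withr::local_tempfile(lines = c(
    "type,feature,mean,sd",
    "A,CA,52.5,0.5",
    "A,CB,19.1,0.6",
    "S,CA,58.3,0.5",
    "S,CB,63.8,0.6"))
  st <- read_statistics_table(f)
  expect_s3_class(st, "type_statistics")
  got <- st[st$type == "A" & st$feature == "CA", ]
  expect_equal(got$mean, 52.5)
  expect_equal(got$sd, 0.5)

  bad_sd <- data.frame(type = c("A", "S"), feature = "CA",
                       mean = c(52.5, 58.3), sd = c(0, 0.5))
  expect_error(type_statistics(bad_sd), "sd")

  dup <- data.frame(type = c("A", "A", "S"), feature = c("CA", "CA", "CA"),
                    mean = c(52.5, 52.6, 58.3), sd = 0.5)
  expect_error(type_statistics(dup), "duplicate")

  # an 18-type table (no G, no P) is a valid training source
  st18 <- benchmark_statistics()
  expect_equal(sort(unique(st18$type)),
               sort(setdiff(c("A","C","D","E","F","G","H","I","K","L","M",
                              "N","P","Q","R","S","T","V","W","Y"),
                            c("G", "P"))))
})

test_that("spin-system CSV round trip keeps missingness", {
  sys <- data.frame(id = c("ss001", "ss002"), res_type = c("A", NA),
                    res_num = c(1L, NA), HN = c(8.2, 8.3),
                    N = c(120.1, 118.4), C = c(176.1, NA),
                    CA = c(52.4, 61.2), CB = c(19.0, NA),
                    TC1_HN = c(-6.1, NA))
  f <- withr::local_tempfile()
  write_spin_systems(sys, f, header_lines = "test fixture")
  back <- read_spin_systems(f)
  expect_equal(back$CA, sys$CA)
  expect_true(is.na(back$C[2]) && is.na(back$TC1_HN[2]))
  expect_true(is.na(back$res_type[2]))
})
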