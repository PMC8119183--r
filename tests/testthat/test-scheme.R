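test_that("complete k-of-n schemes have choose(B, k) rows (factorial oracle)", {
  nck <- function(B, k) factorial(B) / (factorial(k) * factorial(B - k))
  for (B in 1:8) {
    for (k in 1:B) {
      sch <- generate_complete_scheme(sprintf("ch%02d", 1:B), k = k)
      expect_identical(nrow(sch), as.integer(round(nck(B, k))))
      expect_true(all(rowSums(scheme_key_matrix(sch)) == k))
    }
  }
  # the two designs of record
  expect_identical(nrow(generate_complete_scheme(k = 3)), 10L)
  expect_identical(nrow(generate_complete_scheme(c(default_barcode_channels(),
                                                   "89Y"), k = 3)), 20L)
  expect_equal(unname(scheme_key_matrix(
    generate_complete_scheme(c("a", "b", "c"), k = 3))),
    matrix(1L, 1, 3))
})

test_that("rows are lexicographic, deterministic, and pairwise Hamming >= 2", {
  sch <- generate_complete_scheme(k = 3)
  key <- scheme_key_matrix(sch)
  # lexicographic order of positive index sets
  sets <- apply(key, 1L, function(r) unname(which(r == 1L)), simplify = FALSE)
  expect_identical(sets[[1]], c(1L, 2L, 3L))
  expect_identical(sets[[10]], c(3L, 4L, 5L))
  ranks <- vapply(sets, function(s) sum(s * 100^(2:0)), 0)
  expect_true(all(diff(ranks) > 0))
  # deterministic regeneration
  expect_identical(key, scheme_key_matrix(generate_complete_scheme(k = 3)))
  # brute force over all 45 pairs: min Hamming distance exactly 2
  pairs <- combn(nrow(key), 2L)
  hd <- apply(pairs, 2L, function(p) sum(key[p[1], ] != key[p[2], ]))
  expect_identical(min(hd), 2L)
  for (B in 4:6) {
    k2 <- generate_complete_scheme(sprintf("c%d", 1:B), k = 2)
    km <- scheme_key_matrix(k2)
    pr <- combn(nrow(km), 2L)
    expect_true(all(apply(pr, 2L, function(p) sum(km[p[1], ] != km[p[2], ])) >= 2))
  }
})

test_that("parameter validation rejects k out of range", {
  expect_error(generate_complete_scheme(k = 0), class = "cytobarcode_parameter_error")
  expect_error(generate_complete_scheme(k = 6), class = "cytobarcode_parameter_error")
  expect_error(generate_complete_scheme(character(0), k = 1),
               class = "cytobarcode_parameter_error")
})

test_that("validate_scheme returns violations as data", {
  expect_identical(nrow(validate_scheme(scheme10)), 0L)

  dup <- scheme10
  dup[2, default_barcode_channels()] <- dup[1, default_barcode_channels()]
  v <- validate_scheme(dup)
  expect_true("duplicate key" %in% v$rule)

  light <- scheme10
  light[3, "116Cd"] <- 0L
  v2 <- validate_scheme(light)
  expect_true("row weight != k" %in% v2$rule)
  expect_true(3L %in% unlist(v2$rows[v2$rule == "row weight != k"]))

  # Hamming distance 1 (only reachable with non-constant weights)
  near <- scheme10[1:2, ]
  near[2, ] <- near[1, ]
  near[2, "114Cd"] <- 0L
  attr(near, "k") <- 3L
  attr(near, "channels") <- default_barcode_channels()
  class(near) <- class(scheme10)
  v3 <- validate_scheme(near)
  expect_true("Hamming distance < 2" %in% v3$rule)
})

test_that("key files roundtrip exactly and malformed cells are parse errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_key_file(scheme10, path)
  back <- read_key_file(path)
  expect_identical(scheme_key_matrix(back), scheme_key_matrix(scheme10))
  expect_identical(scheme_channels(back), scheme_channels(scheme10))
  expect_identical(back$sample, scheme10$sample)
  expect_identical(scheme_k(back), 3L)
  expect_identical(nrow(validate_scheme(back)), 0L)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,c1,c2,c3", "s1,1,1,0", "s2,1,2,0"), bad)
  err <- expect_error(read_key_file(bad), class = "cytobarcode_parse_error")
  expect_match(conditionMessage(err), "row 2")
  expect_match(conditionMessage(err), "c2")

  hand <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,x,y,z", "a,1,1,0", "b,0,1,1", "c,1,0,1"), hand)
  expect_identical(nrow(validate_scheme(read_key_file(hand))), 0L)

  # partial schemes are flagged informationally, not rejected
  part <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,x,y,z", "a,1,1,0", "b,0,1,1"), part)
  expect_message(read_key_file(part), "partial scheme")
})

test_that("tidy() pivots a scheme to long form", {
  td <- tidy(scheme10)
  expect_identical(nrow(td), 50L)
  expect_named(td, c("sample", "channel", "positive"))
  expect_identical(sum(td$positive), 30L)
})
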