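# m-sequence generation, verification and circular extension

test_that("the order-3 LFSR with taps {3,2} reproduces the hand-enumerated period", {
  m <- generate_msequence(3, c(3, 2), c(1, 1, 1))
  # enumerating the 7 register states by hand gives outputs 1110010
  expect_identical(m$values, c(1L, 1L, 1L, -1L, -1L, 1L, -1L))
  expect_equal(sum(m$values == 1L), 4)
  expect_equal(sum(m$values == -1L), 3)
  # a different primitive polynomial gives a different, still valid, period
  m2 <- generate_msequence(3, c(3, 1), c(1, 1, 1))
  expect_false(identical(m$values, m2$values))
  expect_true(verify_msequence(m2)$pass)
})

test_that("non-primitive taps and degenerate states are rejected with the observed period", {
  expect_error(generate_msequence(4, c(4, 2)), "period 6 < 15")
  expect_error(generate_msequence(3, c(3, 2), c(0, 0, 0)), "all zero")
  expect_error(generate_msequence(3, c(2, 1)), "highest stage")
})

test_that("every catalog polynomial yields a maximal-length sequence", {
  for (order in msequence_orders()) {
    if (order > 12) next  # larger orders are spot-checked below
    m <- generate_msequence(order, rollkernel:::.mseq_catalog[[
      as.character(order)]][[1]])
    expect_length(m$values, 2^order - 1)
  }
  m16 <- generate_msequence(16, c(16, 15, 13, 4))
  expect_length(m16$values, 65535)
})

test_that("random draws are reproducible, length-correct, and verify", {
  set.seed(42)
  a <- random_msequence(8)
  set.seed(42)
  b <- random_msequence(8)
  expect_identical(a$values, b$values)
  expect_length(a$values, 255)
  set.seed(7)
  for (i in 1:25) {
    m <- random_msequence(sample(3:10, 1))
    expect_true(verify_msequence(m)$pass)
  }
  expect_error(random_msequence(99), "not in the supported catalog")
})

test_that("verify_msequence separates valid sequences from corrupted ones", {
  m <- generate_msequence(3, c(3, 2))
  expect_true(verify_msequence(m$values)$pass)
  # degenerate: all +1 fails balance and uniqueness
  v <- verify_msequence(rep(1, 7))
  expect_false(v$balance)
  expect_false(v$subword_unique)
  # one flipped sign breaks the shift-product closure
  bad <- m$values
  bad[4] <- -bad[4]
  expect_false(verify_msequence(bad)$shift_product)
  # wrong length reports a reason instead of throwing
  v2 <- verify_msequence(c(1, -1, 1, 1))
  expect_false(v2$pass)
  expect_match(v2$reason, "2\\^n - 1")
})

test_that("circular autocorrelation is N at lag 0 and -1 elsewhere (orders 3-8)", {
  for (order in 3:8) {
    m <- generate_msequence(order, rollkernel:::.mseq_catalog[[
      as.character(order)]][[1]])
    n <- length(m$values)
    ac <- vapply(0:(n - 1), function(k) {
      sum(m$values * m$values[((seq_len(n) - 1 + k) %% n) + 1])
    }, numeric(1))
    expect_equal(ac[1], n)
    expect_true(all(ac[-1] == -1))
  }
})

test_that("circular extension ends on a full period and handles edge cases", {
  set.seed(3)
  m <- random_msequence(8)
  ext <- extend_circular(m, 400)
  # the final 255 entries are exactly one full period
  expect_identical(ext[146:400], m$values)
  expect_identical(extend_circular(m, 255), m$values)
  m3 <- generate_msequence(3, c(3, 2))
  tail7 <- extend_circular(m3, 10)[4:10]
  expect_true(verify_msequence(tail7)$pass)
  expect_error(extend_circular(m3, 5), "must be >=")
})

test_that("m-sequences round-trip through CSV and JSON", {
  set.seed(9)
  m <- random_msequence(6)
  csv <- tempfile(fileext = ".csv")
  json <- tempfile(fileext = ".json")
  write_msequence(m, csv)
  write_msequence(m, json)
  expect_identical(read_msequence(csv), m$values)
  m2 <- read_msequence(json)
  expect_identical(m2$values, m$values)
  expect_identical(m2$taps, m$taps)
  unlink(c(csv, json))
})
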