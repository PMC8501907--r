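# column-name translation and unit enforcement

test_that("instrument dialects translate to canonical names", {
  raw <- data.frame(PHOTO = c(10, 12), PARi = c(500, 1500), extra = 1:2)
  st <- standardize_columns(raw, c(A_net = "PHOTO", Q = "PARi"))
  expect_named(st, c("A_net", "Q", "extra"))
  expect_equal(st$A_net, raw$PHOTO)
  expect_equal(attr(st, "unmapped"), "extra")

  # identity map leaves an already-canonical table's content unchanged
  canon <- tibble::tibble(A_net = 1:3, Q = 4:6)
  st2 <- standardize_columns(canon, c(A_net = "A_net", Q = "Q"))
  attr(st2, "varnames") <- NULL
  attr(st2, "unmapped") <- NULL
  expect_equal(st2, canon)

  # shipped maps carry the documented instrument headers
  expect_equal(unname(varnames("licor6400")[["A_net"]]), "Photo")
  expect_equal(unname(varnames("licor6800")[["A_net"]]), "A")
})

test_that("bad varname maps raise named errors", {
  raw <- data.frame(PHOTO = 1)
  expect_error(standardize_columns(raw, c(A_net = "FOO")), "FOO")
  expect_error(
    standardize_columns(data.frame(a = 1, b = 2),
                        c(A_net = "a", A_net = "b")),
    "one canonical name")
  expect_error(
    standardize_columns(data.frame(a = 1), c(A_net = "a", Q = "a")),
    "more than once")
})

test_that("renaming round-trips bit-exactly", {
  raw <- data.frame(Photo = rnorm(5), Ci = runif(5, 100, 400), junk = letters[1:5])
  vn <- c(A_net = "Photo", C_i = "Ci")
  st <- standardize_columns(raw, vn)
  back <- as.data.frame(st)
  attr(back, "varnames") <- NULL
  attr(back, "unmapped") <- NULL
  names(back)[match(names(vn), names(back))] <- unname(vn)
  expect_equal(back, raw)
  expect_identical(back$Photo, raw$Photo)
})

test_that("units convert to canonical and conversion is idempotent", {
  tb <- tibble::tibble(T_leaf = 25, RH = 65, A_net = 12)
  out <- enforce_units(tb, c(T_leaf = "degC", RH = "%"))
  expect_equal(out$T_leaf, 298.15)
  expect_equal(out$RH, 0.65)
  expect_equal(unname(attr(out, "units")[["T_leaf"]]), "K")
  # applying again without new declarations changes nothing
  out2 <- enforce_units(out)
  expect_equal(as.data.frame(out2), as.data.frame(out))

  tb2 <- tibble::tibble(A_net = 0.012)
  expect_equal(enforce_units(tb2, c(A_net = "mmol m-2 s-1"))$A_net, 12)
})

test_that("unit errors are caught", {
  tb <- tibble::tibble(g_sw = 0.2)
  expect_error(enforce_units(tb, c(g_sw = "MPa")), "incompatible")
  expect_error(enforce_units(tb, c(g_sw = "furlongs")), "unknown unit")
})

test_that("physical-range validation warns and errors appropriately", {
  expect_warning(
    validate_standard_table(tibble::tibble(T_leaf = 25)),
    "Kelvin")
  expect_error(
    validate_standard_table(tibble::tibble(T_leaf = -5)),
    "0 K")
  expect_error(validate_standard_table(tibble::tibble(RH = 65)), "RH")
  expect_error(validate_standard_table(tibble::tibble(PLC = 120)), "PLC")
})

test_that("CSV reader/writer round-trips with JSON sidecar", {
  td <- withr::local_tempdir()
  raw <- data.frame(A = c(10.5, 12.1), Qin = c(500, 1500),
                    Tleaf = c(25, 25.2))
  raw_path <- file.path(td, "licor.csv")
  utils::write.csv(raw, raw_path, row.names = FALSE)
  st <- read_gas_exchange(raw_path, varnames = "licor6800",
                          declared_units = c(T_leaf = "degC"))
  expect_true(all(c("A_net", "Q", "T_leaf") %in% names(st)))
  expect_equal(st$T_leaf, raw$Tleaf + 273.15)

  out_path <- file.path(td, "canonical.csv")
  write_standard_table(st, out_path)
  expect_true(file.exists(out_path))
  sidecar <- jsonlite::read_json(paste0(out_path, ".json"))
  expect_equal(sidecar$units$T_leaf, "K")
  expect_equal(sidecar$varnames$A_net, "A")
})
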