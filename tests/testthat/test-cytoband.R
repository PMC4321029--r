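test_that("band tokens parse into structured coordinates", {
  b <- parse_band("46C7")
  expect_equal(b$division, 46L)
  expect_equal(b$letter, "C")
  expect_equal(b$band, 7L)
  expect_equal(b$arm, "2R")
  expect_equal(b$chromosome, 2L)

  b <- parse_band("61A")
  expect_equal(b$division, 61L)
  expect_equal(b$letter, "A")
  expect_true(is.na(b$band))
  expect_equal(b$arm, "3L")

  t <- parse_band("3Rt")
  expect_equal(t$telomere, "3R")
  expect_equal(t$chromosome, 3L)

  expect_error(parse_band("20A"), "21-100")
  expect_error(parse_band("101"), "21-100")
  expect_error(parse_band("46G1"), "malformed")
  expect_error(parse_band("xyz"), "malformed")
  # a band number requires a letter: "467" reads as division 467, rejected
  expect_error(parse_band("467"), "21-100")
})

test_that("breakpoint ranges resolve suffix inheritance", {
  r <- parse_band_range("49C1-4")
  expect_equal(format(r$lo), "49C1")
  expect_equal(format(r$hi), "49C4")

  r <- parse_band_range("46C9-46C11")
  expect_equal(format(r), "46C9-46C11")

  r <- parse_band_range("50C23-D2")
  expect_equal(format(r$hi), "50D2")

  r <- parse_band_range("77B-C")
  expect_equal(format(r$hi), "77C")

  # compact double-letter token spans two subdivisions
  r <- parse_band_range("45DE3")
  expect_equal(format(r$lo), "45D")
  expect_equal(format(r$hi), "45E3")

  # single band: degenerate range
  r <- parse_band_range("46C7")
  expect_identical(format(r), "46C7")

  expect_error(parse_band_range("46C7-46C1"), "descending")
})

test_that("deficiency descriptors parse and validate", {
  d <- parse_deficiency("Df(2R)X1", "46C;47A1")
  expect_equal(format(maximal_extent(d)), "46C-47A1")
  expect_equal(d$chromosome, 2L)

  d <- parse_deficiency("Df(2R)M41A4", "41A;41A")
  expect_equal(format(maximal_extent(d)), "41A")

  # stray comma and pointwise "-" separators from printed tables
  d <- parse_deficiency("Df(2R)k10408", "54B16,54B16")
  expect_equal(format(maximal_extent(d)), "54B16")
  d <- parse_deficiency("Df(2L)spd[j2]", "27B2-27F2")
  expect_equal(format(d$proximal), "27B2")
  expect_equal(format(d$distal), "27F2")

  expect_error(parse_deficiency("X", "47A1;46C1"), "descending")
  expect_error(parse_deficiency("X", "46C;61A"), "two chromosomes")
  expect_error(parse_deficiency("X", "46C"), "';' separator")
})

test_that("minimal extent is contained in maximal extent, empty when
           breakpoint uncertainty swallows it", {
  d <- parse_deficiency("Df(2R)CX1", "49C1-4;50C23-D2")
  expect_equal(format(maximal_extent(d)), "49C1-50D2")
  expect_equal(format(minimal_extent(d)), "49C4-50C23")

  # overlapping uncertainty ranges: nothing is certainly deleted
  d <- parse_deficiency("Df(2R)50C-36", "50C19-23;50C21-D5")
  expect_null(minimal_extent(d))

  # containment for every deficiency of the packaged screen table
  t1 <- load_table1()
  for (i in which(!is.na(t1$breakpoints))) {
    d <- parse_deficiency(t1$line_id[i], t1$breakpoints[i])
    mx <- maximal_extent(d)
    mn <- minimal_extent(d)
    if (!is.null(mn)) {
      expect_true(!is.null(df_intersect(mx, mn)))
      expect_identical(format(df_intersect(mx, mn)), format(mn))
    }
  }
})

test_that("every breakpoint string of the packaged tables parses and
           round-trips through formatting", {
  t1 <- load_table1()
  sm <- load_submap()
  bps <- c(t1$breakpoints, sm$breakpoints)
  ids <- c(t1$line_id, sm$line_id)
  keep <- !is.na(bps)
  for (i in which(keep)) {
    d <- parse_deficiency(ids[i], bps[i])
    canon <- paste0(format(d$proximal), ";", format(d$distal))
    d2 <- parse_deficiency(ids[i], canon)
    expect_identical(format(d2), format(d), info = bps[i])
  }
})

test_that("band ordering is a deterministic total order", {
  expect_true(band_le(parse_band("46C1"), parse_band("46C7")))
  expect_true(band_le(parse_band("46C7"), parse_band("47A1")))
  expect_false(band_le(parse_band("47A1"), parse_band("46C7")))
  # telomere sentinel beats every concrete band on its arm
  expect_true(band_le(parse_band("99D3"), parse_band("3Rt")))
  expect_false(band_le(parse_band("3Rt"), parse_band("100F5")))
  # letter-only token sorts at the proximal edge of its subdivision
  expect_true(band_le(parse_band("46C"), parse_band("46C1")))
  expect_error(band_le(parse_band("46C1"), parse_band("61A")),
               "different chromosomes")

  # property: antisymmetry and transitivity on random bands
  set.seed(101)
  rand_band <- function() {
    div <- sample(21:60, 1)
    if (runif(1) < 0.2) return(parse_band(as.character(div)))
    letter <- sample(LETTERS[1:6], 1)
    if (runif(1) < 0.3) return(parse_band(paste0(div, letter)))
    parse_band(paste0(div, letter, sample(1:15, 1)))
  }
  for (rep in 1:200) {
    a <- rand_band(); b <- rand_band(); cc <- rand_band()
    expect_true(band_le(a, b) || band_le(b, a))
    if (band_le(a, b) && band_le(b, a)) {
      expect_identical(f1screen:::.band_start(a), f1screen:::.band_start(b))
    }
    if (band_le(a, b) && band_le(b, cc)) expect_true(band_le(a, cc))
  }
})

test_that("parsed screen breakpoints agree with an independently computed
           genomic sort", {
  t1 <- load_table1()
  labels <- unique(unlist(lapply(which(!is.na(t1$breakpoints)), function(i) {
    d <- parse_deficiency(t1$line_id[i], t1$breakpoints[i])
    c(format(d$proximal$lo), format(d$distal$hi))
  })))
  # oracle sort key computed from the raw text, not the package's encoding
  key <- vapply(labels, function(lab) {
    if (grepl("t$", lab)) {
      arm <- substr(lab, 1, 2)
      return(c("2L" = 40.9, "2R" = 60.9, "3L" = 80.9, "3R" = 100.9)[[arm]])
    }
    m <- regmatches(lab, regexec("^([0-9]+)([A-F])?([0-9]+)?$", lab))[[1]]
    as.integer(m[2]) +
      (if (nzchar(m[3])) match(m[3], LETTERS) / 10 else 0) +
      (if (nzchar(m[4])) as.integer(m[4]) / 1000 else 0)
  }, numeric(1))
  for (chrom in c(2L, 3L)) {
    on_chrom <- labels[vapply(labels, function(l)
      parse_band(l)$chromosome == chrom, logical(1))]
    oracle_order <- on_chrom[order(key[on_chrom])]
    bands <- lapply(oracle_order, parse_band)
    for (i in seq_len(length(bands) - 1)) {
      expect_true(band_le(bands[[i]], bands[[i + 1]]),
                  info = paste(oracle_order[i], oracle_order[i + 1]))
    }
  }
})

test_that("overlap is reflexive, symmetric on maximal extents, and FALSE
           across chromosomes", {
  x1 <- parse_deficiency("Df(2R)X1", "46C;47A1")
  bsc298 <- parse_deficiency("Df(2R)BSC298", "46B2;46C7")
  vgc <- parse_deficiency("Df(2R)vg-C", "49B2;49E2")
  chr3 <- parse_deficiency("Df(3L)ZN47", "64C;65C")
  expect_true(df_overlaps(x1, bsc298))
  expect_true(df_overlaps(bsc298, x1))
  expect_false(df_overlaps(x1, vgc))
  expect_true(df_overlaps(x1, x1))
  expect_false(df_overlaps(x1, chr3))
})

test_that("intersection reproduces the stepwise hotspot reduction", {
  x1 <- parse_deficiency("Df(2R)X1", "46C;47A1")
  bsc152 <- parse_deficiency("Df(2R)BSC152", "46C1;46D7")
  bsc298 <- parse_deficiency("Df(2R)BSC298", "46B2;46C7")
  vgc <- parse_deficiency("Df(2R)vg-C", "49B2;49E2")
  step1 <- df_intersect(x1, bsc152)
  expect_equal(format(step1), "46C1-46D7")
  step2 <- df_intersect(step1, bsc298)
  expect_equal(format(step2), "46C1-46C7")
  expect_null(df_intersect(x1, vgc))
})

test_that("intersection matches discrete set intersection on a synthetic
           map", {
  map <- oracle_map()
  set.seed(202)
  for (rep in 1:150) {
    r1 <- random_range_labels(map)
    r2 <- random_range_labels(map)
    got <- df_intersect(parse_band_range(paste(r1, collapse = "-")),
                        parse_band_range(paste(r2, collapse = "-")))
    want <- intersect(oracle_labels(oracle_band_set(r1[1], r1[2], map)),
                      oracle_labels(oracle_band_set(r2[1], r2[2], map)))
    if (is.null(got)) {
      expect_length(want, 0)
    } else {
      expect_identical(oracle_labels(oracle_band_set(format(got$lo),
                                                     format(got$hi), map)),
                       want)
    }
  }
})

test_that("subtraction keeps breakpoint bands and matches the discrete
           oracle up to retained boundaries", {
  js <- parse_band_range("23C1-23E2")
  ex <- parse_band_range("23C5-23E3")
  pieces <- range_subtract(js, ex)
  expect_length(pieces, 1)
  expect_equal(format(pieces[[1]]), "23C1-23C5")

  expect_length(range_subtract(js, js), 0)

  x1span <- parse_band_range("46C-47A1")
  inner <- parse_band_range("46C9-46C11")
  pieces <- range_subtract(x1span, inner)
  expect_length(pieces, 2)
  expect_equal(format(pieces[[1]]), "46C-46C9")
  expect_equal(format(pieces[[2]]), "46C11-47A1")

  # property: completeness and soundness on the synthetic map. A piece may
  # retain the subtracted interval's own boundary bands (the break may fall
  # inside them) but never its strict interior.
  map <- oracle_map()
  set.seed(303)
  for (rep in 1:150) {
    r1 <- random_range_labels(map)
    r2 <- random_range_labels(map)
    pieces <- range_subtract(parse_band_range(paste(r1, collapse = "-")),
                             parse_band_range(paste(r2, collapse = "-")))
    covered <- unlist(lapply(pieces, function(p)
      oracle_labels(oracle_band_set(format(p$lo), format(p$hi), map))))
    in1 <- oracle_labels(oracle_band_set(r1[1], r1[2], map))
    in2 <- oracle_labels(oracle_band_set(r2[1], r2[2], map))
    expect_true(all(setdiff(in1, in2) %in% covered))
    expect_true(all(covered %in% in1))
    # any subtracted-range band still covered must be one of its boundaries
    expect_true(all(intersect(covered, in2) %in% r2))
    # pieces come out in proximal-to-distal order
    if (length(pieces) == 2) {
      expect_true(band_le(pieces[[1]]$hi, pieces[[2]]$lo))
    }
  }
})
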