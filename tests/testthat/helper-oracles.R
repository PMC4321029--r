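# Independent oracles and tiny synthetic-map helpers for property tests.
#
# The discrete oracle works on a synthetic polytene map with a FIXED number
# of numbered bands per lettered subdivision, so interval operations can be
# checked against plain set arithmetic on enumerated bands. All oracle code
# computes positions from (division, letter, band) tuples directly and never
# calls the package's interval engine.

ORACLE_BANDS_PER_LETTER <- 6L

# enumerate every concrete band of a division range as "div/letter/band" rows
oracle_map <- function(div_lo = 21L, div_hi = 30L) {
  expand.grid(
    band = seq_len(ORACLE_BANDS_PER_LETTER),
    letter = LETTERS[1:6],
    division = div_lo:div_hi,
    stringsAsFactors = FALSE
  )[, c("division", "letter", "band")]
}

# linear index of a concrete band on the oracle map (its own coordinate
# system, independent of the package's key encoding)
oracle_pos <- function(division, letter, band) {
  (division * 6L + match(letter, LETTERS[1:6]) - 1L) *
    ORACLE_BANDS_PER_LETTER + band
}

oracle_pos_of_label <- function(label) {
  m <- regmatches(label, regexec("^([0-9]+)([A-F])([0-9]+)$", label))[[1]]
  oracle_pos(as.integer(m[2]), m[3], as.integer(m[4]))
}

band_label <- function(division, letter, band) paste0(division, letter, band)

# discrete band set covered by an inclusive concrete-endpoint range
oracle_band_set <- function(lo_label, hi_label, map) {
  pos <- oracle_pos(map$division, map$letter, map$band)
  map[pos >= oracle_pos_of_label(lo_label) &
        pos <= oracle_pos_of_label(hi_label), , drop = FALSE]
}

oracle_labels <- function(set) band_label(set$division, set$letter, set$band)

# random concrete-endpoint band range on the oracle map, as labels
random_range_labels <- function(map) {
  i <- sort(sample(nrow(map), 2, replace = TRUE))
  c(band_label(map$division[i[1]], map$letter[i[1]], map$band[i[1]]),
    band_label(map$division[i[2]], map$letter[i[2]], map$band[i[2]]))
}

# pooled-variance two-sample two-tailed t-test, coded from the textbook
# formula (independent of stats::t.test)
oracle_t_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(tstat), df = nx + ny - 2)
}

# two-pass sample standard deviation
oracle_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

load_table1 <- function() read_screen_tsv(f1screen_fixture("table1_screen.tsv"))
load_submap <- function() read_submap_tsv(f1screen_fixture("table2_submap.tsv"))
load_genes <- function() read_annotation_tsv(f1screen_fixture("table2_genes.tsv"))
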