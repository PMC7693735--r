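# Brute-force classic MDR oracle: cells are high-risk when the cell's
# case/control ratio exceeds the overall ratio (empty cells and ties low);
# balanced accuracy is the count-based (sensitivity + specificity) / 2.
# Kept deliberately independent of the package's score-residual machinery.
mdr_oracle <- function(geno_cols, y) {
  geno_cols <- as.matrix(geno_cols)
  key <- apply(geno_cols, 1L, paste, collapse = ",")
  ok <- !apply(geno_cols, 1L, anyNA) & !is.na(y)
  key <- key[ok]; y <- y[ok]
  n_case <- sum(y == 1); n_ctrl <- sum(y == 0)
  cells <- unique(key)
  high <- vapply(cells, function(cl) {
    ca <- sum(y[key == cl] == 1)
    co <- sum(y[key == cl] == 0)
    ca * n_ctrl > co * n_case
  }, logical(1))
  high_cells <- cells[high]
  tp <- sum(y == 1 & key %in% high_cells)
  tn <- sum(y == 0 & !(key %in% high_cells))
  list(high_cells = high_cells,
       ba = (tp / n_case + tn / n_ctrl) / 2)
}

# Tuple string keys for comparing against package integer keys.
oracle_key_to_int <- function(cells) {
  vapply(strsplit(cells, ","), function(d) {
    sum(as.numeric(d) * 3^(seq_along(d) - 1))
  }, numeric(1))
}
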