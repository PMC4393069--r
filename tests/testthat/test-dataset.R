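# Dataset curation: site parsing, lysine labeling, window extraction,
# deduplication, balancing.

test_that("read_sites parses records and rejects bad lines with line numbers", {
  df <- read_sites(text = "P1\t5\tmodified\nP2\t9\tunmodified")
  expect_equal(nrow(df), 2L)
  expect_identical(df$accession, c("P1", "P2"))
  expect_identical(df$position, c(5L, 9L))
  expect_identical(df$status, c("modified", "unmodified"))
  expect_equal(nrow(read_sites(text = "")), 0L)
  expect_error(read_sites(text = "P1\tfive\tmodified"), "line 1")
  expect_error(read_sites(text = "P1\t5\tmodified\nP2\t3\tmaybe"), "line 2")
  expect_error(read_sites(text = "P1\t5"), "fewer than 3")
})

test_that("label_lysines yields one annotation per K with the right statuses", {
  ann <- label_lysines("AKA", modified_positions = 2)
  expect_equal(nrow(ann), 1L)
  expect_identical(ann$status, "modified")

  ann <- label_lysines("KAK")
  expect_equal(nrow(ann), 2L)
  expect_identical(ann$status, c("unmodified", "unmodified"))
  expect_identical(ann$position, c(1L, 3L))

  expect_error(label_lysines("AKA", modified_positions = 1), "not index a lysine")

  # property: positives + negatives always equals the lysine count
  set.seed(42)
  for (i in 1:20) {
    seq <- paste(sample(c("A", "K", "E", "V"), 50, replace = TRUE), collapse = "")
    kpos <- which(strsplit(seq, "")[[1]] == "K")
    mod <- if (length(kpos) > 0) sample(kpos, min(2, length(kpos))) else integer(0)
    ann <- label_lysines(seq, mod)
    expect_equal(nrow(ann), length(kpos))
    expect_equal(sum(ann$status == "modified") + sum(ann$status == "unmodified"),
                 length(kpos))
  }
})

test_that("resolve_sites treats conflicting reports as modified", {
  df <- read_sites(text = "P1\t5\tmodified\nP1\t5\tunmodified\nP1\t9\tunmodified")
  res <- resolve_sites(df)
  expect_equal(nrow(res), 2L)
  expect_identical(res$status[res$position == 5], "modified")
  expect_identical(res$status[res$position == 9], "unmodified")
})

test_that("extract_window returns centered windows with terminus padding", {
  seq21 <- paste0(strrep("A", 10), "K", strrep("E", 10))
  expect_identical(extract_window(seq21, 11, 10), seq21)
  expect_identical(extract_window("KAAA", 1, 3), "XXXKAAA")
  expect_identical(extract_window("MVKIE", 3, 2), "MVKIE")
  expect_identical(extract_window("MVK", 3, 2), "MVKXX")
  expect_error(extract_window("MVKIE", 2, 2), "not 'K'")
  expect_error(extract_window("MVKIE", 9, 2), "outside")

  # property: length and center are invariant
  set.seed(7)
  for (i in 1:25) {
    len <- sample(5:40, 1)
    chars <- sample(c("A", "E", "V"), len, replace = TRUE)
    p <- sample(len, 1)
    chars[p] <- "K"
    fl <- sample(1:10, 1)
    w <- extract_window(paste(chars, collapse = ""), p, fl)
    expect_equal(nchar(w), 2 * fl + 1)
    expect_identical(substr(w, fl + 1, fl + 1), "K")
  }
})

test_that("window_dataset enforces its invariants", {
  expect_error(window_dataset("AKA", "positive", flank = 2), "length 5")
  expect_error(window_dataset("AAA", "positive"), "centered on 'K'")
  expect_error(window_dataset("AKA", "maybe"), "positive")
  ws <- window_dataset(c("AKA", "EKE"), c("positive", "negative"))
  expect_equal(ws_flank(ws), 1L)
})

test_that("deduplicate collapses exact duplicates, modified wins, idempotent", {
  ws <- window_dataset(
    c("AAKEE", "AAKEE", "VVKEE", "AAKEE"),
    c("negative", "positive", "negative", "negative"),
    accession = c("P1", "P2", "P3", "P4"),
    position = c(5L, 8L, 2L, 9L)
  )
  dd <- deduplicate(ws)
  expect_equal(nrow(dd), 2L)
  expect_identical(dd$peptide, c("AAKEE", "VVKEE"))       # input order preserved
  expect_identical(dd$label, c("positive", "negative"))   # conflict -> positive
  expect_identical(dd$accession, c("P1", "P3"))           # first-seen provenance
  expect_identical(deduplicate(dd), dd)                   # idempotent
  # all-unique input is untouched
  uniq <- window_dataset(c("AAKAA", "EEKEE"), c("positive", "negative"))
  expect_identical(deduplicate(uniq)$peptide, uniq$peptide)
})

test_that("balance keeps all positives and a seeded equal-size negative sample", {
  set.seed(1)
  n_pos <- 5L; n_neg <- 40L
  peps <- c(replicate(n_pos, paste0(paste(sample(c("A","E","V"), 2, TRUE), collapse=""), "K",
                                    paste(sample(c("A","E","V"), 2, TRUE), collapse=""))),
            replicate(n_neg, paste0(paste(sample(c("G","S","T"), 2, TRUE), collapse=""), "K",
                                    paste(sample(c("G","S","T"), 2, TRUE), collapse=""))))
  ws <- window_dataset(peps, c(rep("positive", n_pos), rep("negative", n_neg)))
  b1 <- balance(ws, seed = 99)
  expect_equal(sum(b1$label == "positive"), n_pos)
  expect_equal(sum(b1$label == "negative"), n_pos)
  expect_true(all(b1$peptide[b1$label == "positive"] %in% peps[1:n_pos]))
  b2 <- balance(ws, seed = 99)
  expect_identical(b1$peptide, b2$peptide)                # seeded determinism
  expect_equal(attr(b1, "balance_seed"), 99L)
  # equal classes pass through with membership unchanged
  eq <- window_dataset(peps[c(1:5, 6:10)], c(rep("positive", 5), rep("negative", 5)))
  be <- balance(eq, seed = 1)
  expect_setequal(be$peptide, eq$peptide)
  # more positives than negatives is an error
  flipped <- window_dataset(peps, c(rep("negative", n_pos), rep("positive", n_neg)))
  expect_error(balance(flipped, seed = 1), "cannot balance")
})

test_that("build_windows runs FASTA + sites through to labeled windows", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">P1 test protein", "MVKIEAAKAA", ">P2", "KEEEEKAAAA"), fa)
  seqs <- read_fasta_sequences(fa)
  expect_identical(names(seqs), c("P1", "P2"))
  sites <- read_sites(text = "P1\t3\tmodified")
  ws <- build_windows(seqs, sites, flank = 2)
  # P1 has K at 3, 8; P2 has K at 1, 6 -> four windows, one positive
  expect_equal(nrow(ws), 4L)
  expect_equal(sum(ws$label == "positive"), 1L)
  expect_identical(ws$peptide[ws$accession == "P1" & ws$position == 3], "MVKIE")
  expect_identical(ws$peptide[ws$accession == "P2" & ws$position == 1], "XXKEE")
  expect_error(build_windows(seqs, read_sites(text = "NOPE\t1\tmodified"), flank = 2),
               "unknown accession")
})

test_that("non-standard residues are mapped to X with a warning", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">P1", "MVKBZE"), fa)
  expect_warning(seqs <- read_fasta_sequences(fa), "non-standard")
  expect_identical(unname(seqs["P1"]), "MVKXXE")
})

test_that("window TSV round-trips", {
  ws <- window_dataset(c("AAKEE", "VVKEE"), c("positive", "negative"),
                       accession = c("P1", "P2"), position = c(3L, 7L))
  path <- tempfile(fileext = ".tsv")
  write_windows_tsv(ws, path)
  back <- read_windows_tsv(path)
  expect_identical(back$peptide, ws$peptide)
  expect_identical(back$label, ws$label)
  expect_identical(back$position, ws$position)
})
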