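test_that("spacer scanning finds the printed guide in its toy context", {
  hits <- find_spacer_sites("GGATATCCACACCCATGGTGAGG")
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$spacer, "GATATCCACACCCATGGTG")
  expect_equal(fwd$pam, "AGG")
  expect_equal(fwd$position, 1L)
})

test_that("spacer scanning respects PAM structure and strand symmetry", {
  expect_equal(nrow(find_spacer_sites("ATATATATATATATATATATATATAT")), 0)
  s <- withr::with_seed(5, random_dna(300))
  h_fwd <- find_spacer_sites(s)
  h_rev <- find_spacer_sites(revcomp_chr(s))
  expect_equal(sum(h_fwd$strand == "+"), sum(h_rev$strand == "-"))
  expect_equal(sum(h_fwd$strand == "-"), sum(h_rev$strand == "+"))
  expect_setequal(h_fwd$spacer, h_rev$spacer)
  # too-short input
  expect_equal(nrow(find_spacer_sites("ACGTGG")), 0)
})

test_that("spacer scanning equals a brute-force regex oracle", {
  withr::with_seed(17, {
    for (k in 1:5) {
      s <- random_dna(1000)
      hits <- find_spacer_sites(s, spacer_length = 20)
      fwd_oracle <- regex_spacer_starts(s, 20, "NGG")
      rev_oracle <- regex_spacer_starts(revcomp_chr(s), 20, "NGG")
      expect_equal(sort(hits$position[hits$strand == "+"]), sort(fwd_oracle))
      expect_equal(sort(hits$position[hits$strand == "-"]),
                   sort(nchar(s) - rev_oracle - 20L))
    }
  })
})

test_that("global alignment reproduces simple gap structures", {
  id <- align_read("ACGTACGT", "ACGTACGT")
  expect_equal(id$score, 8)
  expect_false(grepl("-", id$read_aln))

  ref <- "ACGTACGTACGT"
  read <- "ACGTAGTACGT"  # 1-base deletion
  al <- align_read(read, ref)
  expect_equal(al$ref_aln, ref)
  expect_equal(nchar(gsub("[^-]", "", al$read_aln)), 1)

  del3 <- align_read("ACGTACGT", "ACGTTTTACGT")  # 3-base deletion, one run
  gaps <- gregexpr("-+", del3$read_aln)[[1]]
  expect_equal(length(gaps), 1)
  expect_equal(attr(gaps, "match.length"), 3)

  allN <- align_read("NNNN", "ACGT")
  expect_equal(allN$score, -4)

  expect_error(align_read("", "ACGT"), "empty read")
})

test_that("alignment scores equal the Biostrings dynamic-programming oracle", {
  skip_if_not_installed("Biostrings")
  withr::with_seed(23, {
    for (k in 1:25) {
      n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
      a <- random_dna(n1); b <- random_dna(n2)
      expect_equal(align_read(a, b)$score, biostrings_score(a, b),
                   info = paste(a, b))
    }
    # longer, more realistic amplicons
    for (k in 1:5) {
      ref <- random_dna(150)
      read <- simulate_amplicon_reads(ref, 75, n_reads = 1,
                                      indel_spectrum = c("-4" = 0.5, "2" = 0.5),
                                      seed = k)$seq
      expect_equal(align_read(read, ref)$score, biostrings_score(read, ref))
    }
  })
})

test_that("indel calls classify reading-frame consequences in the window", {
  ref <- strrep("ACGT", 30)
  no_gap <- align_read(ref, ref)
  expect_equal(call_indel(no_gap, 60)$classification, "unedited")

  del3 <- align_read(apply_del(ref, 60, 3), ref)
  call3 <- call_indel(del3, 60)
  expect_equal(call3$net_indel, -3L)
  expect_equal(call3$classification, "in_frame")

  ins1 <- align_read(paste0(substr(ref, 1, 60), "A", substr(ref, 61, 120)), ref)
  call1 <- call_indel(ins1, 60)
  expect_equal(call1$net_indel, 1L)
  expect_equal(call1$classification, "frameshift")

  # an indel far outside the window is not attributed to the cut site
  del_far <- align_read(apply_del(ref, 5, 2), ref)
  expect_equal(call_indel(del_far, 60, window = 20)$classification, "unedited")
})

test_that("clone summaries recover simulated ground truth exactly", {
  ref <- withr::with_seed(33, random_dna(120))
  reads <- simulate_amplicon_reads(
    ref, 60, n_reads = 200,
    indel_spectrum = c("-3" = 0.25, "-1" = 0.3, "1" = 0.15, "-6" = 0.1),
    unedited_fraction = 0.2, seed = 34)
  s <- summarize_clone(reads, ref, 60, clone_id = "Cl2")
  truth <- table(reads$true_class)
  expect_equal(s$n_unedited, unname(truth["unedited"]), ignore_attr = TRUE)
  expect_equal(s$n_in_frame, unname(truth["in_frame"]), ignore_attr = TRUE)
  expect_equal(s$n_frameshift, unname(truth["frameshift"]), ignore_attr = TRUE)
  expect_equal(s$frameshift_fraction, unname(truth["frameshift"]) / 200,
               ignore_attr = TRUE)
})

test_that("clone classification applies the frameshift threshold", {
  ref <- withr::with_seed(35, random_dna(100))
  clean <- simulate_amplicon_reads(ref, 50, n_reads = 30,
                                   unedited_fraction = 1,
                                   indel_spectrum = numeric(0), seed = 36)
  s0 <- summarize_clone(clean, ref, 50)
  expect_equal(s0$frameshift_fraction, 0)
  expect_equal(s0$clone_class, "low")

  all_fs <- simulate_amplicon_reads(ref, 50, n_reads = 30,
                                    indel_spectrum = c("-1" = 1), seed = 37)
  s1 <- summarize_clone(all_fs, ref, 50)
  expect_equal(s1$frameshift_fraction, 1)
  expect_equal(s1$clone_class, "high")
})

test_that("frameshift fractions follow the simulated spectrum statistically", {
  ref <- withr::with_seed(38, random_dna(100))
  reads <- simulate_amplicon_reads(ref, 50, n_reads = 400,
                                   indel_spectrum = c("-3" = 0.5, "-1" = 0.5),
                                   seed = 39)
  s <- summarize_clone(reads, ref, 50)
  expect_lt(abs(s$frameshift_fraction - 0.5), 3 * sqrt(0.25 / 400))
})
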