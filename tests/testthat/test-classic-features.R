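test_that("GC content is the G+C percentage", {
  expect_identical(gc_content("ACGT"), 50)
  expect_identical(gc_content("AATT"), 0)
  expect_identical(gc_content("GGGCCC"), 100)
})

test_that("stop-codon counts are overlapping substrings, population sd", {
  expect_identical(stop_codon_std("TAATAGTGA"), 0)
  expect_identical(stop_codon_std("CCCCCC"), 0)
  expect_equal(stop_codon_std("TAATAA"), sqrt(8 / 9))
})

test_that("longest-ORF search handles the canonical cases", {
  orf <- find_longest_orf("ATGAAATAG")
  expect_identical(orf$start, 0)
  expect_identical(orf$end, 9)
  expect_true(orf$has_start && orf$has_stop)
  expect_identical(orf$peptide, "MK")

  expect_null(find_longest_orf("CCCCCC"))

  partial <- find_longest_orf("ATGAAA")
  expect_identical(partial$end, 6)
  expect_false(partial$has_stop)
  expect_identical(partial$peptide, "MK")
})

test_that("longest-ORF search matches exhaustive enumeration", {
  set.seed(12)
  for (i in 1:150) {
    s <- random_dna(sample(3:600, 1))
    got <- find_longest_orf(s)
    ref <- oracle_longest_orf(s)
    if (is.null(ref)) {
      expect_null(got)
    } else {
      expect_identical(got$start, ref$start)
      expect_identical(got$end, ref$end)
      expect_identical(got$has_stop, ref$has_stop)
    }
  }
})

test_that("ORF peptide translates from the ORF nucleotides", {
  set.seed(13)
  for (i in 1:40) {
    s <- random_dna(sample(60:500, 1))
    orf <- find_longest_orf(s)
    if (is.null(orf)) next
    nt <- substr(s, orf$start + 1, orf$end)
    codons <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
    if (orf$has_stop) codons <- codons[-length(codons)]
    aa <- paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
    expect_identical(orf$peptide, aa)
  }
})

test_that("ORF integrity and coverage codes follow their definitions", {
  full <- find_longest_orf("ATGAAATAG")
  part <- find_longest_orf("ATGAAA")
  expect_identical(orf_fullness(full), 1)
  expect_identical(orf_fullness(part), 0.5)
  expect_identical(orf_fullness(NULL), 0)
  seq90 <- paste0("ATGAAATAG", strrep("C", 81))
  expect_identical(cds_percent(seq90, find_longest_orf(seq90)), 10)
  expect_identical(cds_percent("ATGAAATAG", full), 100)
  expect_identical(cds_percent("CCC", NULL), 0)
})

test_that("CDS surrogate score follows its formula and grows with span", {
  expect_identical(cds_score("CCC", NULL), 0)
  # complete 300-bp ORF without Kozak context: span + 50 + 50
  body <- strrep("AAA", 98)
  s <- paste0("TTT", "ATG", body, "TAG", "TTT")  # -3 is T: no Kozak bonus
  orf <- find_longest_orf(s)
  expect_identical(orf$end - orf$start, 300)
  expect_identical(cds_score(s, orf), 400)
  # Kozak context (A at -3, G at +4) adds 25
  k <- paste0("AAA", "ATG", "GAA", body, "TAG", "TTT")
  expect_identical(cds_score(k, find_longest_orf(k)),
                   303 + 50 + 50 + 25)
  # monotone in ORF length
  set.seed(14)
  lens <- sort(sample(5:200, 10))
  scores <- vapply(lens, function(nc) {
    s <- paste0("TTT", "ATG", strrep("GCA", nc), "TAA")
    cds_score(s, find_longest_orf(s))
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("isoelectric point zeroes the net charge and orders correctly", {
  pka <- utils::read.delim(system.file("extdata", "pka_emboss.tsv",
                                       package = "lncwave"))
  net_charge <- function(peptide, ph) {
    res <- strsplit(peptide, "")[[1]]
    counts <- c(Nterm = 1, Cterm = 1,
                C = sum(res == "C"), D = sum(res == "D"),
                E = sum(res == "E"), H = sum(res == "H"),
                K = sum(res == "K"), R = sum(res == "R"),
                Y = sum(res == "Y"))
    q <- 0
    for (i in seq_len(nrow(pka))) {
      g <- pka$group[i]
      q <- q + if (pka$charge[i] == "positive") {
        counts[[g]] / (1 + 10^(ph - pka$pka[i]))
      } else {
        -counts[[g]] / (1 + 10^(pka$pka[i] - ph))
      }
    }
    q
  }
  for (pep in c("GG", "MKHR", "DDEEY", "ACDEFGHIKLMNPQRSTVWY")) {
    ph <- isoelectric_point(pep)
    expect_lt(abs(net_charge(pep, ph)), 1e-2)
  }
  expect_lt(isoelectric_point("DDDD"), isoelectric_point("GGGG"))
  expect_lt(isoelectric_point("GGGG"), isoelectric_point("KKKK"))
  expect_identical(isoelectric_point(""), 0)
  expect_error(isoelectric_point("GZ"), "unknown residue")
})

test_that("isoelectric point matches a fine-grid sign-change search", {
  for (pep in c("GG", "KDE", "MKKHRC")) {
    expect_equal(isoelectric_point(pep), oracle_pi_grid(pep),
                 tolerance = 1e-2)
  }
})

test_that("Fickett score stays inside the attainable table range", {
  tabs <- utils::read.delim(system.file("extdata", "fickett_tables.tsv",
                                        package = "lncwave"))
  bound <- function(f) {
    sum(vapply(c("A", "C", "G", "T"), function(b) {
      wp <- tabs$prob[tabs$kind == "weight_position" & tabs$base == b]
      wc <- tabs$prob[tabs$kind == "weight_content" & tabs$base == b]
      f(tabs$prob[tabs$kind == "position" & tabs$base == b]) * wp +
        f(tabs$prob[tabs$kind == "content" & tabs$base == b]) * wc
    }, numeric(1)))
  }
  set.seed(15)
  for (i in 1:30) {
    sc <- fickett_score(random_dna(sample(3:500, 1)))
    expect_gte(sc, bound(min))
    expect_lte(sc, bound(max))
  }
  expect_error(fickett_score("AC"), "shorter than 3")
})

test_that("Fickett score matches the independent lookup oracle", {
  set.seed(16)
  for (i in 1:25) {
    s <- random_dna(sample(10:400, 1))
    expect_equal(fickett_score(s), oracle_fickett(s))
  }
})

test_that("perfect 3-periodicity outscores its shuffle; rotations tie", {
  periodic <- strrep("ACG", 40)
  set.seed(17)
  shuffled <- paste(sample(strsplit(periodic, "")[[1]]), collapse = "")
  expect_gt(fickett_score(periodic), fickett_score(shuffled))
  rots <- c(strrep("ACG", 40), strrep("CGA", 40), strrep("GAC", 40))
  scores <- vapply(rots, fickett_score, numeric(1))
  expect_equal(max(scores), min(scores))
})

test_that("the eight classic features assemble finitely with sentinels", {
  row <- classic_features(strrep("A", 300))
  expect_true(all(is.finite(row)))
  expect_identical(unname(row["Orf_fullness"]), 0)
  expect_identical(unname(row["CDS_Score"]), 0)
  expect_identical(unname(row["CDS_percent"]), 0)
  expect_identical(unname(row["PI"]), 0)
  expect_identical(names(row),
                   c("seq_len", "GC_content", "Stop_std", "Orf_fullness",
                     "CDS_Score", "CDS_percent", "PI", "Fickett_Score"))
})
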