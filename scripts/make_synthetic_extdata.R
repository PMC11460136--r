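# Regenerates the packaged synthetic reference alignments under
# inst/extdata/ (run from the repository root). Two accessions per species,
# planted diagnostic columns at the canonical assay positions, and a few
# screening-relevant blemishes (ambiguity code, shared gap, intra-species
# polymorphism) that must be excluded by the column rules.

set.seed(20260929 %% 1000003)

targets <- c(FCIR = "Fritillaria cirrhosa", FUNI = "Fritillaria unibracteata",
             FPRZ = "Fritillaria przewalskii", FDEL = "Fritillaria delavayi",
             FTAI = "Fritillaria taipaiensis", FWAB = "Fritillaria wabuensis")
adulterants <- c(FHUP = "Fritillaria hupehensis", FUSS = "Fritillaria ussuriensis",
                 FTHU = "Fritillaria thunbergii", FPAL = "Fritillaria pallidiflora",
                 FWAL = "Fritillaria walujewii")
species <- c(targets, adulterants)

make_locus <- function(len, plant) {
  backbone <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  seqs <- list()
  for (code in names(species)) {
    for (acc in 1:2) {
      s <- backbone
      for (p in plant) {
        s[p$pos] <- if (code %in% p$carriers) p$allele else p$other
      }
      seqs[[paste0(code, acc)]] <- s
    }
  }
  seqs
}

its <- make_locus(450, list(
  list(pos = 341, carriers = names(targets), allele = "T", other = "C"),
  list(pos = 361, carriers = "FTHU", allele = "C", other = "T"),
  list(pos = 366, carriers = "FUSS", allele = "G", other = "A"),
  list(pos = 200, carriers = character(0), allele = "A", other = "A")
))
its[["FCIR1"]][50] <- "R"
its[["FTHU1"]][100] <- "-"
its[["FTHU2"]][100] <- "-"
its[["FDEL2"]][200] <- "G"

matk <- make_locus(1250, list(
  list(pos = 336, carriers = names(targets), allele = "A", other = "G"),
  list(pos = 923, carriers = "FHUP", allele = "A", other = "G"),
  list(pos = 1173, carriers = c("FPAL", "FWAL"), allele = "A", other = "T")
))
matk[["FUSS1"]][10] <- "N"
matk[["FPAL1"]][600] <- "-"
matk[["FPAL2"]][600] <- "-"

write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  for (id in names(seqs)) {
    code <- substr(id, 1, 4)
    writeLines(sprintf(">%s %s", id, species[[code]]), con)
    s <- paste(seqs[[id]], collapse = "")
    starts <- seq(1, nchar(s), by = 60)
    writeLines(substring(s, starts, pmin(starts + 59, nchar(s))), con)
  }
  close(con)
}

write_fasta(its, "inst/extdata/synthetic_its_aln.fasta")
write_fasta(matk, "inst/extdata/synthetic_matk_aln.fasta")

jsonlite::write_json(list(
  name = "FCB",
  target_group = unname(targets),
  adulterants = unname(adulterants),
  joint_taxa = list(FPB = unname(c(adulterants[["FPAL"]], adulterants[["FWAL"]])))
), "inst/extdata/fcb_grouping.json", auto_unbox = TRUE, pretty = TRUE)

cat("wrote inst/extdata\n")
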