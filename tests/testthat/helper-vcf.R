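# Minimal hand-built multi-sample VCF for reader/filter unit tests.
# Three clones of one cell line; FORMAT GT:AD:DP:GQ (plus :SR on SV rows).

write_mini_vcf <- function(rows, samples = c("PR1A", "PR1B", "PR1C"),
                           path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    "##FILTER=<ID=LowQual,Description=\"x\">",
    "##INFO=<ID=PAF,Number=1,Type=Float,Description=\"x\">",
    "##INFO=<ID=MAP,Number=1,Type=Integer,Description=\"x\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"x\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"x\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"x\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"x\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"x\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"x\">",
    "##FORMAT=<ID=SR,Number=1,Type=Integer,Description=\"x\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, rows), path)
  path
}

# convenience: a passing SNV row genotyped in one clone
vcf_row <- function(pos, ref = "A", alt = "T", filter = "PASS",
                    info = "MAP=1", format = "GT:AD:DP:GQ",
                    s1 = "0/1:20,20:40:60", s2 = "0/0:40,0:40:60",
                    s3 = "0/0:40,0:40:60") {
  paste("chr1", pos, ".", ref, alt, ".", filter, info, format,
        s1, s2, s3, sep = "\t")
}

mini_treatments <- c(PR1A = "proton", PR1B = "helium", PR1C = "control")
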