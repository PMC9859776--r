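# One-off generator for the packaged hallmark protein fixture set
# (inst/extdata/hallmark_proteins_synthetic.faa). The sequences are synthetic:
# fixed random proteins with soil-protein-like residue frequencies standing in
# for a curated database of AOA-provirus capsid/terminase/portal/integrase
# (and MCO1 AMG) queries. Regenerate only if the fixture design changes; the
# shipped file is part of the package contract (cassette sequences in
# generated genomes are back-translated copies of these).

set.seed(20260923)

aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
# approximate average proteome residue frequencies
freq <- c(8.3, 5.5, 4.0, 5.5, 1.4, 3.9, 6.8, 7.1, 2.3, 6.0,
          9.7, 5.8, 2.4, 3.9, 4.7, 6.6, 5.4, 1.1, 2.9, 6.9)
freq <- freq / sum(freq)

# enough AOA queries that every default-scenario virus (and every host
# provirus remnant) can carry a distinct query, disjoint between soils
kinds <- c(capsid = 16L, terminase = 16L, portal = 16L, integrase = 28L,
           mco1 = 6L)
# guild of the provirus each query putatively derives from
guild_plan <- function(kind, n) {
  if (kind == "mco1") rep("AOA", n)
  else c(rep("AOA", n - 4L), rep("AOB", 2L), rep("NOB", 2L))
}

lines <- character(0)
for (kind in names(kinds)) {
  n <- kinds[[kind]]
  guilds <- guild_plan(kind, n)
  for (i in seq_len(n)) {
    len <- sample(150:400, 1L)
    body <- sample(aa, len - 1L, replace = TRUE, prob = freq)
    seq <- paste0("M", paste(body, collapse = ""))
    id <- sprintf("%s|%s|%02d", kind, guilds[i], i)
    lines <- c(lines, paste0(">", id, " synthetic hallmark query"),
               gsub("(.{70})", "\\1\n", seq))
  }
}
writeLines(lines, "inst/extdata/hallmark_proteins_synthetic.faa")
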