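# fixtures built in code, shared across test files

# a small simulated dataset cached per test run
quick_cfg <- function(..., seed = 99) {
  sim_config(n_mothers = 40, n_markers = 80, n_families = 4,
             n_years = 8, progeny_per_mother = 2, records_per_progeny = 2,
             seed = seed, ...)
}

# continuous genotypes straight from integer read matrices
cg_from_counts <- function(ra, rb) {
  continuous_genotypes(gbsblup:::new_read_depths(ra = ra, rb = rb))
}

# small GBLUP problem with a well-conditioned dosage-based G
small_problem <- function(n_mothers = 30, traits = 1, seed = 51,
                          trait_missing_rate = 0) {
  VM <- diag(3, traits); VC <- diag(2, traits); VE <- diag(8, traits)
  if (traits == 2) { VM[1, 2] <- VM[2, 1] <- 1.2; VE[1, 2] <- VE[2, 1] <- 2 }
  cfg <- sim_config(n_mothers = n_mothers, n_markers = 200,
                    n_families = 3, V_M = VM, V_C = VC, V_E = VE,
                    n_years = 6, progeny_per_mother = 2,
                    records_per_progeny = 2,
                    trait_missing_rate = trait_missing_rate, seed = seed)
  genos <- simulate_population(cfg)
  G <- dosage_grm(genos) + diag(0.05, n_mothers)
  phen <- simulate_phenotypes(genos, G, cfg)
  list(cfg = cfg, G = G, data = phen$data,
       vc = variance_components(VM, VC, VE, cfg$trait_names))
}

# hand-written VCF: 3 samples x 4 biallelic SNPs with enumerated AD values,
# plus one tri-allelic record and one record without any depth field
write_fixture_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\tm1\tA\tC\t.\t.\t.\tAD\t3,1\t0,0\t5,0",
    "1\t200\tm2\tG\tT\t.\t.\t.\tAD\t2,2\t10,0\t1,3",
    "1\t250\tbad1\tG\tT,A\t.\t.\t.\tAD\t2,2,1\t1,0,0\t1,3,2",
    "1\t300\tm3\tC\tA\t.\t.\t.\tGT:AD\t0/1:4,4\t./.:0,0\t0/0:6,2",
    "1\t350\tbad2\tT\tA\t.\t.\t.\tGT\t0/1\t0/0\t1/1",
    "1\t400\tm4\tT\tG\t.\t.\t.\tAD\t0,7\t1,1\t2,0"
  ), path)
  path
}

# expected AD matrices for the fixture above (samples x markers)
fixture_ra <- function() {
  matrix(c(3, 0, 5,  2, 10, 1,  4, 0, 6,  0, 1, 2), nrow = 3,
         dimnames = list(c("S1", "S2", "S3"), c("m1", "m2", "m3", "m4")))
}
fixture_rb <- function() {
  matrix(c(1, 0, 0,  2, 0, 3,  4, 0, 2,  7, 1, 0), nrow = 3,
         dimnames = list(c("S1", "S2", "S3"), c("m1", "m2", "m3", "m4")))
}
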