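# Fixture builders shared across tests.

# minimal sample table: reps samples per treatment per strain
make_sample_table <- function(strains = c("B", "N", "D"),
                              treatments = c("NH", "CMS", "NH-R", "CMS-R"),
                              reps = 2) {
  g <- expand.grid(rep = seq_len(reps), treatment = treatments,
                   strain = strains, stringsAsFactors = FALSE)
  data.frame(sample_id = paste(g$strain, g$treatment, g$rep, sep = "_"),
             strain = g$strain, treatment = g$treatment,
             stringsAsFactors = FALSE)
}

# rows of a passing-call table for one membership region
region_calls <- function(ids, strains, directions) {
  do.call(rbind, lapply(seq_along(strains), function(i) {
    data.frame(transcript = ids, strain = strains[i], shape = "TRANSIENT",
               direction = directions[[i]], template_p = 0.01, q = 0.5,
               contrast_p = 0.01, rel_change = ifelse(directions[[i]] == "UP",
                                                      0.5, -0.5),
               passes = TRUE, stringsAsFactors = FALSE)
  }))
}

# call-set fixture reproducing the printed exclusive Venn region sizes:
# B-only 430, N-only 258, D-only 1363, B:N 9, B:D 31, N:D 130, triple 6.
# Directions follow the printed member lists where the text gives them:
# all 9 B:N transcripts concordant (4 up, 5 down); 3 of 31 B:D concordant
# (1 down, 2 up); 15 of 130 N:D concordant (11 down, 4 up); all 6 triple
# transcripts up in B and N and down in D.
make_printed_overlap_calls <- function() {
  id <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))
  rbind(
    region_calls(id("bo", 430), "B",
                 list(rep(c("UP", "DOWN"), length.out = 430))),
    region_calls(id("no", 258), "N",
                 list(rep(c("UP", "DOWN"), length.out = 258))),
    region_calls(id("do", 1363), "D",
                 list(rep(c("UP", "DOWN"), length.out = 1363))),
    make_bn_concordance_calls(prefix = "bn"),
    make_bd_concordance_calls(prefix = "bd"),
    make_nd_concordance_calls(prefix = "nd"),
    region_calls(id("tr", 6), c("B", "N", "D"),
                 list(rep("UP", 6), rep("UP", 6), rep("DOWN", 6)))
  )
}

# B:N shared transcripts: 4 up-regulated and 5 down-regulated in both
# substrains (9 of 9 concordant)
make_bn_concordance_calls <- function(prefix = "bn") {
  up <- c("Kcnn3", "Kcnk9", "Sgsm1", "Mir344")
  down <- c("Srl", "Orai2", "Fam220-ps", "Zcchc5", "Slain1os")
  ids <- paste0(prefix, "_", c(up, down))
  dirs <- c(rep("UP", 4), rep("DOWN", 5))
  region_calls(ids, c("B", "N"), list(dirs, dirs))
}

# B:D shared transcripts: 31 total, 3 concordant (Fkbp5 down in both,
# Mir6415 and 1700019G24Rik up in both), 28 discordant
make_bd_concordance_calls <- function(prefix = "bd") {
  conc_ids <- paste0(prefix, "_", c("Fkbp5", "Mir6415", "1700019G24Rik"))
  conc_dirs <- c("DOWN", "UP", "UP")
  disc_ids <- sprintf("%s_disc%02d", prefix, 1:28)
  disc_b <- rep(c("UP", "DOWN"), length.out = 28)
  disc_d <- ifelse(disc_b == "UP", "DOWN", "UP")
  rbind(
    region_calls(conc_ids, c("B", "D"), list(conc_dirs, conc_dirs)),
    region_calls(disc_ids, c("B", "D"), list(disc_b, disc_d))
  )
}

# N:D shared transcripts: 130 total, 15 concordant (11 down: Fn1, Fmo2,
# Mertk, Gkn3, Dbp, Hif3a, Tmc7, Paqr5, Ptprb, Ly6c1, Ly6c; 4 up: Nhlh2,
# Gimap6, Igkv4-58, 3110004A20Rik), 115 discordant
make_nd_concordance_calls <- function(prefix = "nd") {
  down <- c("Fn1", "Fmo2", "Mertk", "Gkn3", "Dbp", "Hif3a", "Tmc7",
            "Paqr5", "Ptprb", "Ly6c1", "Ly6c")
  up <- c("Nhlh2", "Gimap6", "Igkv4-58", "3110004A20Rik")
  conc_ids <- paste0(prefix, "_", c(down, up))
  conc_dirs <- c(rep("DOWN", 11), rep("UP", 4))
  disc_ids <- sprintf("%s_disc%03d", prefix, 1:115)
  disc_n <- rep(c("UP", "DOWN"), length.out = 115)
  disc_d <- ifelse(disc_n == "UP", "DOWN", "UP")
  rbind(
    region_calls(conc_ids, c("N", "D"), list(conc_dirs, conc_dirs)),
    region_calls(disc_ids, c("N", "D"), list(disc_n, disc_d))
  )
}

# a sim_config with no multi-strain overlap blocks
null_overlap_spec <- function() stats::setNames(numeric(0), character(0))
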