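# Shared fixtures: a reduced 9-taxon design, small trees, and a naive
# brute-force CCS classifier kept deliberately independent of the package's
# vectorized implementation.

small_design <- function() {
  species_design("out",
                 fg1 = c("p1a", "p1b"), fg2 = c("p2a", "p2b"),
                 bg1 = c("a1a", "a1b"), bg2 = c("a2a", "a2b"))
}

small_design_taxa <- function()
  c("p1a", "p1b", "p2a", "p2b", "a1a", "a1b", "a2a", "a2b", "out")

# Literal transcription of the CCS rule, one column at a time, no shared
# code with the package: conservativeness = every control residue
# determinately equals the outgroup residue; a convergent call = exactly one
# residue d != O reaching the per-cluster support threshold in both tested
# clusters.
brute_force_ccs <- function(column, design, min_shared, missing = c("-", "X", "?")) {
  O <- column[[design$outgroup]]
  if (O %in% missing)
    return(list(direction = "none", derived = NA_character_))
  eqO <- function(tx) {
    r <- column[tx]
    all(!(r %in% missing)) && all(r == O)
  }
  cons_fg <- eqO(design$bg1) && eqO(design$bg2)
  cons_bg <- eqO(design$fg1) && eqO(design$fg2)
  test <- function(cl1, cl2) {
    hits <- character(0)
    for (d in setdiff(unique(unlist(column)), c(O, missing))) {
      if (sum(column[cl1] == d) >= min_shared &&
          sum(column[cl2] == d) >= min_shared)
        hits <- c(hits, d)
    }
    if (length(hits) == 1L) hits else NA_character_
  }
  if (cons_fg && !cons_bg)
    list(direction = "foreground", derived = test(design$fg1, design$fg2))
  else if (cons_bg && !cons_fg)
    list(direction = "background", derived = test(design$bg1, design$bg2))
  else
    list(direction = "none", derived = NA_character_)
}

five_taxon_tree <- function()
  read_tree(text = "((a:0.12,b:0.25):0.08,(c:0.3,d:0.15):0.06,e:0.4);")

# mirrored event-rich topology used for null-calibration checks
calibration_topology <- function()
  default_topology(tip_length = 0.02, pair_length = 0.02,
                   cluster_stem = 0.6, clade_stem = 0.05,
                   ingroup_stem = 0.05, outgroup_length = 0.02)
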