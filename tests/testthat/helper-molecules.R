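# Shared fixtures built in code: diverse SMILES lists and small utilities.

# a structurally diverse hand-written fixture: aromatics, heteroaromatics,
# carbonyls, amines, alcohols, olefins, fused systems, halogens
diverseSmiles <- function() {
  c("c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "c1ccncc1", "c1ccsc1",
    "c1cc[nH]c1", "c1ccoc1", "c1ccc2ccccc2c1", "c1ccc2ncccc2c1",
    "c1ccc2nccnc2c1", "O=C(c1ccccc1)c1ccccc1", "O=C1c2ccccc2Sc2ccccc21",
    "CC(=O)C(C)=O", "CC(=O)c1ccccc1", "NNc1ccccc1", "Nc1ccccc1",
    "CNc1ccccc1", "CCN", "CCNC", "OCc1ccccc1", "Oc1ccccc1", "CCO",
    "C=C", "C=CC=C", "C=Cc1ccccc1", "C1=CCCCC1", "CC=CC",
    "FC(F)(F)c1ccccc1", "Clc1ccccc1", "Brc1ccccc1", "Ic1ccccc1",
    "COc1ccccc1", "CSc1ccccc1", "O=S(=O)(c1ccccc1)c1ccccc1",
    "N#Cc1ccccc1", "CC#N", "c1ccc(-c2ccccc2)cc1",
    "c1ccc(-c2ccncc2)cc1", "Cn1cccc1", "c1ccc2[nH]c3ccccc3c2c1",
    "O=c1[nH]cnc2[nH]cnc12", "CC(C)Cc1ccccc1", "CCCCCC", "C1CCCCC1",
    "CC1CCCCC1", "OC1CCCCC1", "NC1CCCCC1", "O=C1CCCCC1",
    "COC(=O)C=Cc1ccccc1", "O=C1C=CC(=O)N1c1ccccc1")
}

# deterministic pool of GA-mutated molecules grown from simple seeds;
# exercises the full edit vocabulary
mutatedPool <- function(n = 100L, seed = 7L) {
  base <- lapply(c("c1ccccc1", "c1ccncc1", "Cc1ccccc1", "c1ccsc1"),
                 parseSmiles)
  out <- list()
  photoforge:::.withSeed(seed, {
    pool <- base
    while (length(out) < n) {
      m <- mutateMolecule(pool[[sample.int(length(pool), 1L)]])
      out[[length(out) + 1L]] <- m
      pool[[length(pool) + 1L]] <- m
      if (length(pool) > 40L) pool <- pool[-1L]
    }
  })
  out
}

quietTheta <- function(mol) suppressMessages(fractionConjugated(mol))

obabelAvailable <- function() nzchar(Sys.which("obabel"))

# independent SMARTS match through the OpenBabel CLI (test oracle)
obabelMatches <- function(smi, smarts) {
  out <- suppressWarnings(system2(
    Sys.which("obabel"), c(paste0("-:", shQuote(smi)), "-osmi", "-s",
                           shQuote(smarts)),
    stdout = TRUE, stderr = FALSE))
  any(nzchar(trimws(out)))
}
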