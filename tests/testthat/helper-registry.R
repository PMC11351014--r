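# Shared helpers: registries in temporary files, cleaned up when the
# calling test finishes.

localRegistry <- function(config = registryConfig(), env = parent.frame()) {
  db <- tempfile(fileext = ".sqlite")
  reg <- initRegistry(db, config)
  withr::defer({
    closeRegistry(reg)
    unlink(db)
  }, envir = env)
  reg
}

# canonical SMILES shortcut used by standardization tests
canon <- function(smiles) {
  vapply(smiles, function(s) parseMolecule(s)@smiles, character(1),
         USE.NAMES = FALSE)
}

# count of molecule rows in a registry
moleculeCount <- function(reg) {
  DBI::dbGetQuery(reg@con, "SELECT COUNT(*) AS n FROM molecules")$n[[1L]]
}
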