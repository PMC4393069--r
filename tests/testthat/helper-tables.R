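# Synthetic property tables and small fixtures used across tests.

# A scale assigning a constant value to every residue.
constant_scale <- function(accession, value) {
  v <- rep(value, 20)
  names(v) <- sumohunt:::AAINDEX_RESIDUE_ORDER
  sumohunt:::new_property_scale(accession, paste("constant", value), v)
}

# A scale with explicit per-residue values (defaults filled with `fill`).
custom_scale <- function(accession, values, fill = 0) {
  v <- rep(fill, 20)
  names(v) <- sumohunt:::AAINDEX_RESIDUE_ORDER
  v[names(values)] <- values
  sumohunt:::new_property_scale(accession, "custom", v)
}

# Synthetic 16-scale table where scale i maps every residue to i.
synthetic_table16 <- function() {
  property_table(lapply(1:16, function(i) constant_scale(sprintf("SYN%06d", i), i)))
}

# Tiny window dataset: n7 windows of flank `flank` built from given peptides.
tiny_windows <- function(peptides, labels) {
  window_dataset(peptides, labels)
}

# AAIndex1 text for one entry with coefficients 1..20 in canonical order.
AAINDEX_ONE_TO_TWENTY <- paste(
  "H TEST000001",
  "D coefficients 1..20 in canonical order",
  "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
  "      1.      2.      3.      4.      5.      6.      7.      8.      9.     10.",
  "     11.     12.     13.     14.     15.     16.     17.     18.     19.     20.",
  "//", sep = "\n")
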