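# Scale table provenance

- `eisenberg.csv` — Eisenberg, Schwarz, Komaromy & Wall (1984) normalized
  consensus hydrophobicity scale. J Mol Biol 179:125-142.
- `kyte_doolittle.csv` — Kyte & Doolittle (1982) hydropathy scale
  (GRAVY). J Mol Biol 157:105-132.
- `boman.csv` — residue potential-interaction values used by the Boman
  index (Boman 2003, J Intern Med 254:197-215), derived from Radzicka &
  Wolfenden (1988) transfer free energies; the index is the negated mean.
  Proline carries 0 (not measured), following common descriptor packages.
- `diwv.csv` — Guruprasad, Reddy & Pandit (1990) dipeptide instability
  weight values (DIWV); instability index = 10/L * sum over dipeptides.
  Protein Eng 4:155-161.
- `residue_mass.csv` — average molecular weights of the free amino acids;
  protein MW = sum - (L-1) * 18.0153 (water lost per peptide bond).
- `pka_emboss.csv` — EMBOSS pKa set used for Henderson-Hasselbalch net
  charge and isoelectric point. sign: +1 gains positive charge when
  protonated (bases, N-terminus), -1 gains negative charge when
  deprotonated (acids, C-terminus).
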