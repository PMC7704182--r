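Provenance of npsle_mrs_reference.csv
=====================================

The CSV transcribes the published per-feature group statistics of the
NPSLE-vs-healthy-control multivoxel 1H-MRS study cohort (23 NPSLE patients,
16 healthy controls; 9 brain regions x 13 metabolite measures = 117
features): group mean +/- dispersion in institutional concentration units,
the printed two-sided Mann-Whitney p-value, the printed single-feature ROC
AUC, and the printed asterisk markers ("*" significant, "**" used by the
classifier panel, "***" both), plus two derived 0/1 masks.

The published source does not state whether the "+/-" dispersions are
standard deviations or standard errors of the mean; the CSV stores them
verbatim and consumers choose an interpretation (dispersion_mode).

Corrections applied during transcription
----------------------------------------
1. RLN / Cr, NPSLE mean: printed "8364" transcribed as 8.364.  A raw value
   of 8364 is off by three orders of magnitude from every neighbouring
   entry (HC mean 9.868, dispersion 0.362); a dropped decimal point is the
   only reading consistent with the column.
2. LDT row 3: row label printed "Cr+Cr" transcribed as "Cr+PCr", matching
   the measure list used by every other region block and the 117-feature
   total.
3. LLN row 9: row label printed "mI/Cr+Cr" transcribed as "mI/Cr+PCr",
   same rationale as (2).
4. The region list in the methods prose ("RPCG, LRCG, RDT, RDT, LDT, RLN
   LLN, RPWM, LPWM") contains a typo ("LRCG"), a duplicate ("RDT" twice)
   and omits the right insula; the 9 regions used here are those of the
   results table itself: RPCG, LPCG, RDT, LDT, RLN, LLN, RI, RPWM, LPWM.

Derived masks
-------------
significant (33 features): printed p-value < 0.05.  The published prose
  list and count (33) agree with this rule; four asterisk markers do not
  (e.g. LLN mI carries "*" with p = 0.894, LLN mI/Cr+PCr has p = 0.036 but
  only "**").  The p-value rule is authoritative here; markers are stored
  verbatim in the `marker` column for reference.
selected (26 features): the 26-feature classifier panel named in the
  results prose.  Two entries disagree with the "**"/"***" markers
  (the prose names RPCG Glu+Gln/Cr+PCr and LPWM NAAG but not
  RPCG Cho+PCh/Cr+PCr or LPWM NAA+NAAG); the prose list, whose count
  matches the stated 26, is authoritative.

File integrity: md5 5bf3aba5c658ccceabcc4768b9646325 (checked at load).
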