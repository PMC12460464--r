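# Packaged cohort-count fixtures

Per-cohort subject counts and demographics of the four public multi-site
cohorts these tools are aimed at (ABIDE I: 18 cohorts across 15 sites;
ABIDE II: 11 sites; HBN: 3 sites; AOMIC: 2 resting-state cohorts). Only
the published count tables are shipped — no subject-level data. Use
`expand_cohort_counts()` to blow a count table up into a subject-level
manifest with generated ids (diagnosis `unknown`, since the count tables
do not break subjects down by diagnosis).

Totals: ABIDE I 988, ABIDE II 623, HBN 1,385, AOMIC 442.

Note on the ABIDE I total: the source literature states in one place that
ABIDE I comprises 998 subjects from 15 sites and elsewhere 988 subjects;
the per-cohort table sums to 988, so these fixtures carry 988. Both
figures are recorded here deliberately rather than reconciled silently.
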