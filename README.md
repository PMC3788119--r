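# hdxdiff

Differential protection analysis for hydrogen-deuterium exchange mass
spectrometry (HDX-MS), for structural biologists who compare two states of
a protein — typically a monomer against an oligomer or a complex — and want
to know *where* the protein becomes shielded.

The pipeline starts at peptide tables (identifications plus per-replicate
centroid masses, the level at which DynamX-style software exports data) and
ends at residue-level protected regions mapped onto coordinates:

1. **Quality filtering** of peptide identifications (intensity ≥ 3000,
   products ≥ 2, products per amino acid ≥ 0.15, consecutive products ≥ 1)
   and observation matching within ±15 ppm m/z, ±9 s retention time and
   ±2 ion-mobility drift bins.
2. **Fraction of exchange.** Each centroid mass `Mex` is normalized against
   the peptide's in-exchange control (0% reference) and full-deuteration
   out-exchange control (100% reference):

   `f = (Mex − Mex0) / (Mex100 − Mex0)`

   with mean, sample SD and n over ≥ 3 replicates, per charge state.
3. **Differential screen.** `Δ = f_ref − f_test` (positive = more protected
   in the test state), error `σ = sd_ref + sd_test` (linear SD sum;
   quadrature optional), significance `Δ > 2σ` (one-sided), screened at the
   earliest exchange time with confirmation at the next time point.
4. **Region merging** of significant peptide spans (overlapping and
   bookended spans union), sequence coverage, control-equivalence checks.
5. **Structural metrics** on supplied coordinates: Shrake–Rupley SASA,
   per-residue interface burial, hydrophobic burial energetics
   (11.1 cal mol⁻¹ Å⁻² ⇒ 900 Å² ≈ 10 kcal/mol), inter-chain contacts and
   salt bridges, and mapping of protected regions onto the structure.

Because raw data for this kind of study are rarely deposited, the package
includes a forward simulator of two-state EX2 exchange
(`d_i(t) = 1 − exp(−(k_int/P)·t)` per residue, with in-exchange floor α and
back-exchange ceiling β) with known ground truth, so the whole pipeline is
testable by region recovery.

## Worked example

The built-in benchmark simulates a synthetic 304-residue construct
(reported as residues 23–326) whose dimer state multiplies the protection
factors of regions 129–133 (peptides ASEL/SASEL) and 227–237
(PRVWEPVPLE/PRVWEPVPLEE) by 20, with 3 replicates, centroid noise of 0.02
fraction units and exchange times of 10, 60 and 1200 s:

```r
library(hdxdiff)

ds  <- simulate_hdx_dataset(rage_scenario(seed = 42))
rep <- run_hdx_pipeline(ds)
rep
#> HDX differential-protection report (config 61b2824e426cbe561adaf0b82d097ae0)
#>   coverage: 76.3%
#>   differential peptides: 4
#>   protected regions: 2
#> # A tibble: 2 × 5
#>   start   end n_peptides peptides               earliest_time_s
#>   <int> <int>      <int> <chr>                            <dbl>
#> 1   129   133          2 SASEL;ASEL                          10
#> 2   227   237          2 PRVWEPVPLE;PRVWEPVPLEE              10
```

The report says: the accepted digest covers 76.3% of the construct; four
peptides (and only those four) show protection by more than 2σ at the 10 s
screen, confirmed at 60 s; and their spans merge into exactly the two
ground-truth interface regions. `glance(rep)` gives the one-row summary,
`tidy(rep)` the per-peptide/-time calls, `autoplot(rep$screen)` the Woods
plot and `plot_kinetics(rep$fractions, c("SASEL", "PRVWEPVPLEE"))` the
uptake time courses; `write_hdx_report(rep, "out/")` writes the fraction,
Woods and region tables, each stamped with the config hash.

On the structural side:

```r
atoms <- read_structure("dimer.pdb")
bp    <- buried_surface(atoms)            # per-residue ΔSASA + totals
burial_energy(bp)                          # kcal/mol from hydrophobic burial
contact_profile(atoms, "A", "B")           # inter-chain contacts, salt bridges
map_regions_to_structure(rep$regions, atoms)
```

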