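# Ligand structure fixtures

SDF V2000 connection tables for the five ligands used by the similarity
analyses:

| file | compound | formula |
|---|---|---|
| `pomolic_acid.sdf` | pomolic acid (ursane triterpenoid, 3β,19α-diol, 28-oic acid) | C30H48O4 |
| `hederagenin.sdf` | hederagenin (oleanane triterpenoid, 3β,23-diol, 28-oic acid) | C30H48O4 |
| `caulophyllogenin.sdf` | caulophyllogenin (oleanane triterpenoid, 3β,16α,23-triol, 28-oic acid) | C30H48O5 |
| `betulinic_acid.sdf` | betulinic acid (lupane triterpenoid, 3β-ol, 28-oic acid) | C30H48O3 |
| `rosiglitazone.sdf` | rosiglitazone (thiazolidinedione) | C18H19N3O3S |

## Construction

The files were redrawn from the compounds' known constitutions (skeleton,
substituent positions, bond orders) and exported as kekulized V2000 mol
blocks with 2D coordinates. Stereochemistry is deliberately omitted: the
circular-fingerprint similarity these fixtures feed ignores chirality (the
ECFP default), so only the molecular graph matters. Molecular formulas were
verified against the values above; implicit hydrogens are implied by
standard valences, as the package's reader assigns them.

Coordinates are layout-only (2D); nothing in the package reads geometry
from these files.
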