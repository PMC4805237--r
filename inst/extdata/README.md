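# External data

Place the deposited Mangrove Cuckoo specimen table here as
`mangrove_cuckoo_deposit.csv` (CSV, one row per specimen, canonical
column names or a `schema` mapping — see `?read_specimens`) to enable
the validation test that reproduces the published values, and to run
the `analysis/` workflow on the real museum series instead of the
synthetic world. The deposit is published at
doi:10.6084/m9.figshare.1328170 and is not redistributed with this
package.
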