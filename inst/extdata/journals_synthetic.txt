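# SYNTHETIC placeholder journal list (29 invented names).
# Stand-in for a curated list of mycological journals; the real curated
# list is not redistributed with this package. Supply your own list via
# the journals argument/flag for real analyses.
Synthetic Journal of Mycology
Synthetic Mycological Research
Synthetic Fungal Biology
Synthetic Fungal Diversity Letters
Synthetic Studies in Mycology
Synthetic Mycological Progress
Synthetic Fungal Ecology
Synthetic Journal of Fungal Systematics
Synthetic Mycorrhiza Reports
Synthetic Fungal Genetics Bulletin
Synthetic Medical Mycology Notes
Synthetic Yeast Research
Synthetic Lichenological Journal
Synthetic Mycoscience Quarterly
Synthetic Fungal Pathology
Synthetic Mushroom Science
Synthetic Cryptogamie Mycologie
Synthetic Mycotaxon Archive
Synthetic Fungal Kingdom Review
Synthetic Journal of Basidiomycete Studies
Synthetic Ascomycete Monographs
Synthetic Mold and Mildew Letters
Synthetic Journal of Wood Decay Fungi
Synthetic Endophyte Research
Synthetic Aquatic Mycology
Synthetic Soil Fungi Journal
Synthetic Polar Mycology
Synthetic Tropical Fungi Bulletin
Synthetic Experimental Mycology
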