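# Molar (base-10) extinction coefficients of human hemoglobin, cm^-1 / (mol/L).
# Values from the widely used Gratzer/Kollias compilation distributed by
# S. Prahl (Oregon Medical Laser Center, "Optical absorption of hemoglobin"),
# also the tabulation behind Homer's GetExtinctions at these wavelengths.
# Columns: wavelength_nm, eps_hbo (oxyhemoglobin), eps_hbr (deoxyhemoglobin).
wavelength_nm	eps_hbo	eps_hbr
730	390.0	1102.2
850	1058.0	691.32
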