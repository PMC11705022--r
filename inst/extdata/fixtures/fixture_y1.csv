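product_code,retailer_id,brand,brand_type,tra_category,container_size,container_unit,serving_size,serving_unit,price,energy_kcal,fat_g,satfat_g,carb_g,sugars_g,fibre_g,protein_g,sodium_mg,calcium_mg,fvnl_percent,year_label
P01,RA,FIXTURE,private_label_premium,C,500,g,50,g,5.01,50,1.5,0.5,7.5,2,1,2,400,25,0,2017
P02,RA,FIXTURE,private_label_discount,C,500,g,100,g,5.02,100,3,1,15,4,2,4,800,50,0,2017
P03,RA,FIXTURE,multinational,C,500,g,100,g,5.03,100,3,1,15,4,2,4,800,50,0,2017
P04,RA,FIXTURE,domestic_or_other,C,500,g,100,g,5.04,100,3,1,15,4,2,4,800,50,0,2017
P05,RA,FIXTURE,multinational,C,500,g,100,g,5.05,100,3,1,15,4,2,4,800,50,0,2017
P06,RA,FIXTURE,multinational,C,500,g,100,g,5.06,100,3,1,35,30,2,4,80,50,0,2017
P07,RA,FIXTURE,multinational,B,500,ml,100,ml,5.07,40,0,0,10,9,0,0,10,0,0,2017
P08,RA,FIXTURE,multinational,B,500,ml,100,ml,5.08,0,0,0,0,0,0,0,0,0,0,2017
P09,RA,FIXTURE,multinational,B,500,ml,100,ml,5.09,40,0,0,10,9,0,0,10,0,0,2017
P10,RA,FIXTURE,multinational,B,500,ml,100,ml,5.1,40,0,0,10,4.4,0,0,10,0,0,2017
P11,RA,FIXTURE,multinational,H,500,g,100,g,5.11,720,81,50,0.6,0.6,0,0.5,600,20,0,2017
P12,RA,FIXTURE,multinational,D,500,g,100,g,5.12,400,33,21,2,1,0,25,700,800,0,2017
P13,RA,FIXTURE,multinational,D,500,g,100,g,5.13,400,33,21,2,1,0,25,700,300,0,2017
P14,RA,FIXTURE,multinational,V,500,g,100,g,5.14,30,0.3,0.1,5,3,3,2,200,40,100,2017
P15,RA,FIXTURE,multinational,C,500,g,100,g,5.15,100,3,1,15,4,2,4,80,50,0,2017
P16,RA,FIXTURE,multinational,C,500,g,100,g,5.16,100,3,1,15,4,2,4,80,50,0,2017
P17,RA,FIXTURE,multinational,C,500,g,100,g,5.17,100,3,1,15,4,2,4,80,50,0,2017
P18,RA,FIXTURE,multinational,C,500,g,100,g,5.18,100,3,1,15,4,2,4,80,50,0,2017
P19,RA,FIXTURE,multinational,C,500,g,100,g,5.19,100,3,1,15,4,2,4,80,50,0,2017
P20,RA,FIXTURE,multinational,C,500,g,100,g,5.2,100,3,1,15,4,2,4,80,50,0,2017
P21,RA,FIXTURE,multinational,C,500,g,100,g,5.21,100,3,1,15,4,2,4,80,50,0,2017
P22,RA,FIXTURE,multinational,C,500,g,100,g,5.22,100,3,1,15,4,2,4,80,50,0,2017
P23,RA,FIXTURE,multinational,C,500,g,100,g,5.23,100,3,1,15,4,2,4,80,50,0,2017
P24,RA,FIXTURE,multinational,C,500,g,100,g,5.24,100,3,1,15,4,2,4,80,50,0,2017
P25,RA,FIXTURE,multinational,C,500,g,100,g,5.25,100,3,1,15,4,2,4,80,50,0,2017
P26,RA,FIXTURE,multinational,C,500,g,100,g,5.26,100,3,1,15,4,2,4,80,50,0,2017
P27,RA,FIXTURE,multinational,C,500,g,100,g,5.27,100,3,1,15,4,2,4,80,50,0,2017
P28,RA,FIXTURE,multinational,C,500,g,100,g,5.28,100,3,1,15,4,2,4,80,50,0,2017
P29,RA,FIXTURE,multinational,C,500,g,100,g,5.29,100,3,1,15,4,2,4,80,50,0,2017
P30,RA,FIXTURE,multinational,C,500,g,100,g,5.3,100,3,1,15,4,2,4,80,50,0,2017
P31,RA,FIXTURE,multinational,C,500,g,100,g,5.31,100,3,1,15,4,2,4,80,50,0,2017
P32,RA,FIXTURE,multinational,C,500,g,100,g,5.32,100,3,1,15,4,2,4,80,50,0,2017
P33,RA,FIXTURE,multinational,C,500,g,100,g,5.33,100,3,1,15,4,2,4,80,50,0,2017
P34,RA,FIXTURE,multinational,C,500,g,100,g,5.34,100,3,1,15,4,2,4,80,50,0,2017
P35,RA,FIXTURE,multinational,C,500,g,100,g,5.35,100,3,1,15,4,2,4,80,50,0,2017
P36,RA,FIXTURE,multinational,C,500,g,100,g,5.36,100,3,1,15,4,2,4,80,50,0,2017
P37,RA,FIXTURE,multinational,C,500,g,100,g,5.37,100,3,1,15,4,2,4,80,50,0,2017
P38,RA,FIXTURE,multinational,C,500,g,100,g,5.38,100,3,1,15,4,2,4,80,50,0,2017
P39,RA,FIXTURE,multinational,C,500,g,100,g,5.39,100,3,1,15,4,2,4,80,50,0,2017
P40,RA,FIXTURE,multinational,C,500,g,100,g,5.4,100,3,1,15,4,2,4,80,50,0,2017
P41,RA,FIXTURE,multinational,C,500,g,100,g,5.41,100,3,1,15,4,2,4,80,50,0,2017
P42,RA,FIXTURE,multinational,C,500,g,100,g,5.42,100,3,1,15,4,2,4,80,50,0,2017
P43,RA,FIXTURE,multinational,C,500,g,100,g,5.43,100,3,1,15,4,2,4,80,50,0,2017
P52,RA,FIXTURE,multinational,C,500,g,100,g,5.52,100,3,1,15,4,2,4,80,50,0,2017
P44,RA,FIXTURE,multinational,C,500,g,100,g,5.44,100,3,1,15,4,"",4,80,50,0,2017
P45,RA,FIXTURE,multinational,C,500,g,100,g,5.45,100,3,1,15,4,2,4,80,50,0,2017
P46,RA,FIXTURE,multinational,D,500,g,100,g,5.46,400,33,21,2,1,0,25,700,800,0,2017
P47,RA,FIXTURE,multinational,C,500,g,100,g,5.47,100,3,1,15,4,2,4,80,50,0,2017
P48,RA,FIXTURE,multinational,C,500,g,100,g,5.48,"","","","","",2,"","",50,0,2017
P49,RA,FIXTURE,multinational,C,500,g,100,g,5.49,100,3,1,"",4,2,4,80,50,0,2017
P50,RA,FIXTURE,multinational,C,500,g,100,g,5.5,100,3,1,15,4,2,4,80,50,0,2017
P51,RA,FIXTURE,multinational,C,500,g,100,g,0,100,3,1,15,4,2,4,80,50,0,2017
P53,RA,FIXTURE,multinational,W,500,g,100,g,5.53,100,3,1,15,4,2,4,80,50,0,2017
P54,RA,FIXTURE,multinational,X,500,g,100,g,5.54,100,3,1,15,4,2,4,80,50,0,2017
P55,RA,FIXTURE,multinational,C,500,g,100,g,5.55,100,3,1,15,4,2,4,80,50,0,2017
P56,RA,FIXTURE,multinational,C,500,g,100,g,5.56,100,3,1,15,4,2,4,80,50,0,2017
P59,RA,FIXTURE,multinational,C,500,g,100,g,5.59,100,3,1,15,4,2,4,80,50,0,2017
P60,RA,FIXTURE,multinational,C,500,g,100,g,5.6,100,3,1,15,4,2,4,80,50,0,2017
P60,RA,FIXTURE,multinational,C,500,g,100,g,5.6,100,3,1,15,4,2,4,80,50,0,2017
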